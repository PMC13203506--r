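# Eight-dimensional constant-velocity Kalman filter over (cx, cy, a, h) and
# per-frame velocities, the standard motion model of appearance-based MOT.
# Noise scales are height-proportional: position std = h/20, velocity std =
# h/160 per step (the ecosystem-standard completion; the tracking literature
# this follows names the 8-D state space but no matrices).

KF_DIM <- 8L

kf_matrices <- function() {
  F <- diag(8)
  F[1:4, 5:8] <- diag(4)
  H <- cbind(diag(4), matrix(0, 4, 4))
  list(F = F, H = H)
}

#' Initialize a Kalman track state from a measurement
#'
#' @param measurement Numeric length-4 `(cx, cy, a, h)`: box center, aspect
#'   ratio w/h, height in pixels (`h > 0`).
#' @param std_weight_pos,std_weight_vel Noise scale weights relative to box
#'   height (defaults 1/20 and 1/160).
#' @return Object of class `kalman_state`: list with `mean` (length 8,
#'   velocities zero) and `cov` (8 x 8).
#' @export
kf_init <- function(measurement, std_weight_pos = 1 / 20, std_weight_vel = 1 / 160) {
  m <- as.numeric(measurement)
  stopifnot(length(m) == 4)
  if (!is.finite(m[4]) || m[4] <= 0) stop("measurement height must be positive", call. = FALSE)
  h <- m[4]
  std <- c(2 * std_weight_pos * h, 2 * std_weight_pos * h, 1e-2, 2 * std_weight_pos * h,
           10 * std_weight_vel * h, 10 * std_weight_vel * h, 1e-5, 10 * std_weight_vel * h)
  structure(list(mean = c(m, rep(0, 4)), cov = diag(std^2),
                 wp = std_weight_pos, wv = std_weight_vel),
            class = "kalman_state")
}

#' Kalman predict step (constant velocity, one frame)
#' @param state A `kalman_state`.
#' @return Advanced `kalman_state` with covariance `F P F' + Q`.
#' @export
kf_predict <- function(state) {
  M <- kf_matrices()
  h <- state$mean[4]
  std <- c(state$wp * h, state$wp * h, 1e-2, state$wp * h,
           state$wv * h, state$wv * h, 1e-5, state$wv * h)
  state$mean <- drop(M$F %*% state$mean)
  state$cov <- M$F %*% state$cov %*% t(M$F) + diag(std^2)
  state
}

# project state onto measurement space; returns projected mean and innovation
# covariance S = H P H' + R
kf_project <- function(state, noise_inflation = 1) {
  M <- kf_matrices()
  h <- state$mean[4]
  std <- c(state$wp * h, state$wp * h, 1e-1, state$wp * h) * noise_inflation
  S <- M$H %*% state$cov %*% t(M$H) + diag(std^2)
  list(mean = drop(M$H %*% state$mean), S = S)
}

#' Kalman update (correction) step
#'
#' Standard correction of the 4-D position block by a `(cx, cy, a, h)`
#' measurement. `noise_inflation` scales the measurement noise std, used when
#' feeding gap-filled pseudo-measurements.
#'
#' @param state A `kalman_state`.
#' @param measurement Numeric length-4 `(cx, cy, a, h)`.
#' @param noise_inflation Multiplier on the measurement std (default 1).
#' @return Updated `kalman_state`.
#' @export
kf_update <- function(state, measurement, noise_inflation = 1) {
  m <- as.numeric(measurement)
  stopifnot(length(m) == 4)
  M <- kf_matrices()
  pr <- kf_project(state, noise_inflation)
  ch <- tryCatch(chol(pr$S), error = function(e) NULL)
  if (is.null(ch)) stop("singular innovation covariance", call. = FALSE)
  K <- t(backsolve(ch, forwardsolve(t(ch), M$H %*% state$cov)))
  innov <- m - pr$mean
  state$mean <- state$mean + drop(K %*% innov)
  P <- (diag(8) - K %*% M$H) %*% state$cov
  state$cov <- (P + t(P)) / 2
  state
}

#' Squared Mahalanobis gating distance of measurements from a track state
#'
#' @param state A `kalman_state` (typically after [kf_predict()]).
#' @param measurements Numeric matrix, one `(cx, cy, a, h)` row per candidate
#'   (a single length-4 vector is accepted).
#' @param position_only If TRUE use only the `(cx, cy)` block (2 dof).
#' @return Numeric vector of squared Mahalanobis distances.
#' @export
kf_gating_distance <- function(state, measurements, position_only = FALSE) {
  if (is.null(dim(measurements))) measurements <- matrix(measurements, nrow = 1)
  pr <- kf_project(state)
  if (position_only) {
    d <- sweep(measurements[, 1:2, drop = FALSE], 2, pr$mean[1:2])
    S <- pr$S[1:2, 1:2]
  } else {
    d <- sweep(measurements, 2, pr$mean)
    S <- pr$S
  }
  z <- forwardsolve(t(chol(S)), t(d))
  colSums(z^2)
}

#' Chi-square gating threshold (0.95 quantile, 4 dof) used for association
#' @export
GATING_THRESHOLD <- 9.4877

# box (corners) <-> measurement (cx, cy, a, h)
box_to_xyah <- function(b) {
  w <- b[[3]] - b[[1]]; h <- b[[4]] - b[[2]]
  c((b[[1]] + b[[3]]) / 2, (b[[2]] + b[[4]]) / 2, w / h, h)
}

xyah_to_box <- function(m) {
  h <- m[[4]]; w <- m[[3]] * h
  c(m[[1]] - w / 2, m[[2]] - h / 2, m[[1]] + w / 2, m[[2]] + h / 2)
}
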