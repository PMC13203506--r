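# Conflict-coverage mechanism: when two active lockers overlap beyond a
# threshold they are assumed to cover the same animal; the one with the lower
# multi-criteria score (confidence + historical stability + trajectory
# maturity) is removed from the active pool.

#' Detect overlap conflicts among active lockers
#'
#' All unordered pairs of lockers whose boxes have IoU strictly greater than
#' `theta`, each pair reported once.
#'
#' @param lockers Data frame with columns `id`, `x`, `y`, `w`, `h` (one row
#'   per active locker), or a list of `(id, box)` pairs.
#' @param theta Overlap threshold in (0, 1), default 0.5.
#' @return Tibble with columns `id1`, `id2`, `iou`, sorted by decreasing IoU.
#' @export
detect_conflicts <- function(lockers, theta = 0.5) {
  stopifnot(theta > 0, theta < 1)
  df <- tibble::as_tibble(lockers)
  n <- nrow(df)
  if (n < 2) {
    return(tibble::tibble(id1 = integer(0), id2 = integer(0), iou = numeric(0)))
  }
  B <- ltwh_to_corners(df)
  M <- iou_matrix(B, B)
  idx <- which(upper.tri(M) & M > theta, arr.ind = TRUE)
  out <- tibble::tibble(id1 = df$id[idx[, 1]], id2 = df$id[idx[, 2]],
                        iou = M[idx])
  out[order(-out$iou, out$id1, out$id2), ]
}

#' Multi-criteria locker score
#'
#' \deqn{S = \alpha C + \beta H + \gamma L} where `C` is the current
#' detection confidence, `H` the historical stability (fraction of frames
#' with a confirmed detection match) and `L` the normalized trajectory
#' length, all in \[0, 1\].
#'
#' @param conf,stability,maturity The `C`, `H`, `L` components.
#' @param weights Length-3 non-negative vector `(alpha, beta, gamma)` summing
#'   to 1 (default `c(0.4, 0.3, 0.3)`).
#' @return Score in \[0, 1\].
#' @examples
#' score_locker(0.5, 0.8, 0.6) # 0.62
#' @export
score_locker <- function(conf, stability, maturity, weights = c(0.4, 0.3, 0.3)) {
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("score weights must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(all(c(conf, stability, maturity) >= 0), all(c(conf, stability, maturity) <= 1))
  weights[1] * conf + weights[2] * stability + weights[3] * maturity
}

#' Score components of a track
#'
#' `H = N_tracked / N_total` (frames with a confirmed detection match over
#' frames since birth), `L = N_frames / max_frames` (trajectory length
#' normalized over all active trajectories), `C` = most recent detection
#' confidence, 0 while the track is gap-filling.
#'
#' @param track A tracker-internal track (list with counters `n_tracked`,
#'   `n_total`, `n_frames`, `last_conf`, `status`).
#' @param max_frames Maximum `n_frames` over all active trajectories.
#' @return Named list `(conf, stability, maturity)`.
#' @export
compute_score_inputs <- function(track, max_frames) {
  if (track$n_total < 1) stop("uninitialized track: no frames observed", call. = FALSE)
  list(conf = if (identical(track$status, "filling")) 0 else track$last_conf,
       stability = track$n_tracked / track$n_total,
       maturity = track$n_frames / max(1, max_frames))
}

# Resolve all conflicts among active tracks. Multi-way conflicts are handled
# by repeatedly resolving the highest-IoU pair until no pair exceeds theta;
# each pass removes one locker, so this terminates. Score ties break toward
# the lower (older) track id. Returns the ids to remove.
resolve_conflicts <- function(lockers, scores, theta = 0.5) {
  removed <- integer(0)
  df <- tibble::as_tibble(lockers)
  repeat {
    live <- df[!df$id %in% removed, , drop = FALSE]
    conf <- detect_conflicts(live, theta)
    if (nrow(conf) == 0) break
    id1 <- conf$id1[1]; id2 <- conf$id2[1]
    s1 <- scores[[as.character(id1)]]; s2 <- scores[[as.character(id2)]]
    loser <- if (s1 > s2) id2 else if (s2 > s1) id1 else max(id1, id2)
    removed <- c(removed, loser)
  }
  removed
}
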