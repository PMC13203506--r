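# Auxiliary locker: kernelized correlation filter over HOG features.
# Ridge regression over all circular shifts of the template, solved in the
# Fourier domain with a Gaussian kernel; localization by the response-map
# peak, refined to sub-cell precision by trigonometric interpolation
# (zero-padded inverse FFT of the response spectrum).

#' KCF hyper-parameters
#'
#' Canonical published defaults: search window `padding` 1.5x the target box,
#' Gaussian kernel bandwidth `sigma` 0.5, ridge regularization `lambda` 1e-4,
#' online learning rate `eta` 0.02, HOG cell 4 px, regression target width
#' `output_sigma_factor * sqrt(w * h)`. `resp_upsample` is the trigonometric
#' interpolation factor for sub-cell peak refinement.
#'
#' @param padding,sigma,lambda,eta,cell,nbins,output_sigma_factor,resp_upsample
#'   See description.
#' @return Named list of parameters.
#' @export
kcf_params <- function(padding = 1.5, sigma = 0.5, lambda = 1e-4, eta = 0.02,
                       cell = 4L, nbins = 9L, output_sigma_factor = 0.1,
                       resp_upsample = 8L) {
  stopifnot(lambda > 0, eta >= 0, eta <= 1, cell >= 1, padding >= 1)
  list(padding = padding, sigma = sigma, lambda = lambda, eta = eta,
       cell = as.integer(cell), nbins = as.integer(nbins),
       output_sigma_factor = output_sigma_factor,
       resp_upsample = as.integer(resp_upsample))
}

#' Histogram-of-oriented-gradients features
#'
#' Per-cell unsigned gradient-orientation histograms (`nbins` bins over
#' \[0, pi)), with linear interpolation between neighboring orientation bins
#' and per-cell L2 normalization. Deterministic.
#'
#' @param patch Grayscale matrix (color arrays are averaged to gray).
#' @param cell Cell side in pixels (default 4).
#' @param nbins Number of orientation bins (default 9).
#' @return `floor(h/cell) x floor(w/cell) x nbins` feature array.
#' @export
hog_features <- function(patch, cell = 4L, nbins = 9L) {
  patch <- to_gray(patch)
  h <- nrow(patch); w <- ncol(patch)
  if (h < cell || w < cell) stop("patch smaller than one HOG cell", call. = FALSE)
  gx <- (patch[, c(2:w, w), drop = FALSE] - patch[, c(1, 1:(w - 1)), drop = FALSE]) / 2
  gy <- (patch[c(2:h, h), , drop = FALSE] - patch[c(1, 1:(h - 1)), , drop = FALSE]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  nch <- h %/% cell; ncw <- w %/% cell
  binf <- ang / pi * nbins
  b0 <- floor(binf); fb <- binf - b0
  b0 <- b0 %% nbins; b1 <- (b0 + 1) %% nbins
  ci <- (row(patch) - 1L) %/% cell
  cj <- (col(patch) - 1L) %/% cell
  keep <- ci < nch & cj < ncw
  FF <- numeric(nch * ncw * nbins)
  i0 <- (ci + nch * cj + nch * ncw * b0)[keep]
  i1 <- (ci + nch * cj + nch * ncw * b1)[keep]
  a0 <- rowsum((mag * (1 - fb))[keep], i0)
  a1 <- rowsum((mag * fb)[keep], i1)
  FF[as.integer(rownames(a0)) + 1L] <- a0
  FF[as.integer(rownames(a1)) + 1L] <- FF[as.integer(rownames(a1)) + 1L] + a1
  dim(FF) <- c(nch, ncw, nbins)
  nrm <- sqrt(apply(FF^2, c(1, 2), sum)) + 1e-6
  FF / array(nrm, dim(FF))
}

to_gray <- function(patch) {
  d <- dim(patch)
  if (length(d) == 3) {
    g <- patch[, , 1]
    if (d[3] >= 3) g <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
    g
  } else {
    patch
  }
}

hann_window <- function(n1, n2) {
  outer(0.5 * (1 - cos(2 * pi * seq_len(n1) / (n1 + 1))),
        0.5 * (1 - cos(2 * pi * seq_len(n2) / (n2 + 1))))
}

# Gaussian kernel correlation between feature stacks given their per-channel
# FFTs; returns the kernel map in the spatial domain, peaked at the circular
# shift of `af`'s features relative to `bf`'s
gaussian_correlation <- function(af, bf, sigma) {
  n <- length(af[[1]])
  aa <- sum(vapply(af, function(m) sum(Mod(m)^2), 0)) / n
  bb <- sum(vapply(bf, function(m) sum(Mod(m)^2), 0)) / n
  ab <- Re(fft(Reduce(`+`, Map(function(p, q) p * Conj(q), af, bf)), inverse = TRUE)) / n
  k <- exp(-pmax(0, (aa + bb - 2 * ab) / (n * length(af))) / sigma^2)
  dim(k) <- dim(ab)  # pmax drops dim; restore so later ffts stay 2-D
  k
}

fft_shifted_index <- function(n) c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1)))

# train dual coefficients on a prepared (already windowed) feature array
kcf_fit_features <- function(feat, params) {
  d <- dim(feat)
  xf <- lapply(seq_len(d[3]), function(k) fft(feat[, , k]))
  s <- params$output_sigma_factor * sqrt(d[1] * d[2])
  iy <- fft_shifted_index(d[1]); ix <- fft_shifted_index(d[2])
  y <- exp(-outer(iy^2, ix^2, `+`) / (2 * s^2))
  kxx <- gaussian_correlation(xf, xf, params$sigma)
  list(xf = xf, alphaf = fft(y) / (fft(kxx) + params$lambda))
}

# crop an integer window centered at (cx, cy), replicating the border
crop_window <- function(image, cx, cy, win_h, win_w) {
  g <- to_gray(image)
  rows <- round(cy - win_h / 2) + seq_len(win_h)
  cols <- round(cx - win_w / 2) + seq_len(win_w)
  rows <- pmin(pmax(rows, 1L), nrow(g))
  cols <- pmin(pmax(cols, 1L), ncol(g))
  g[rows, cols, drop = FALSE]
}

#' Train a KCF model on a target
#'
#' Extracts a padded search window around `target_box` from `patch`, computes
#' windowed HOG features and solves the kernel ridge regression in the
#' Fourier domain: dual coefficients `alphaf = fft(y) / (fft(kxx) + lambda)`
#' with a Gaussian regression target `y` centered on the box.
#'
#' @param patch Image (matrix or array) containing the target.
#' @param target_box Length-4 corner vector of the target inside `patch`.
#' @param params [kcf_params()].
#' @return Object of class `kcf_model`.
#' @export
kcf_train <- function(patch, target_box, params = kcf_params()) {
  b <- as.numeric(target_box)
  tw <- b[3] - b[1]; th <- b[4] - b[2]
  stopifnot(tw > 0, th > 0)
  cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
  win_w <- max(params$cell * 2L, floor(tw * params$padding / params$cell) * params$cell)
  win_h <- max(params$cell * 2L, floor(th * params$padding / params$cell) * params$cell)
  window <- crop_window(patch, cx, cy, win_h, win_w)
  model <- list(params = params, win_h = win_h, win_w = win_w,
                target_w = tw, target_h = th)
  class(model) <- "kcf_model"
  kcf_fit_window(model, window)
}

# (re)fit a model on a window-sized grayscale patch
kcf_fit_window <- function(model, window) {
  p <- model$params
  feat <- hog_features(window, p$cell, p$nbins)
  hw <- hann_window(dim(feat)[1], dim(feat)[2])
  feat <- feat * array(hw, dim(feat))
  fit <- kcf_fit_features(feat, p)
  model$xf <- fit$xf
  model$alphaf <- fit$alphaf
  model$feat_dim <- dim(feat)
  model
}

#' Localize the target in a new patch
#'
#' The patch must be the same processing size as the training window. Returns
#' the displacement of the response-map peak relative to the window center,
#' refined to sub-cell precision by trigonometric interpolation, plus the
#' peak response value as a tracking-quality score.
#'
#' @param model A `kcf_model`.
#' @param patch Window-sized image patch.
#' @return List with `dx`, `dy` (pixels) and `peak`.
#' @export
kcf_detect <- function(model, patch) {
  p <- model$params
  g <- to_gray(patch)
  if (nrow(g) != model$win_h || ncol(g) != model$win_w) {
    stop("patch size does not match the training window", call. = FALSE)
  }
  feat <- hog_features(g, p$cell, p$nbins)
  if (all(feat == 0)) stop("degenerate input: patch has no gradient energy", call. = FALSE)
  hw <- hann_window(dim(feat)[1], dim(feat)[2])
  feat <- feat * array(hw, dim(feat))
  zf <- lapply(seq_len(dim(feat)[3]), function(k) fft(feat[, , k]))
  kzx <- gaussian_correlation(zf, model$xf, p$sigma)
  resp_f <- fft(kzx) * model$alphaf
  pk <- response_peak(resp_f, p$resp_upsample)
  list(dx = pk[2] * p$cell, dy = pk[1] * p$cell, peak = pk[3])
}

# sub-cell peak localization by zero-padding the response spectrum
response_peak <- function(resp_f, U) {
  n1 <- nrow(resp_f); n2 <- ncol(resp_f)
  N1 <- n1 * U; N2 <- n2 * U
  big <- matrix(0 + 0i, N1, N2)
  h1 <- n1 %/% 2; h2 <- n2 %/% 2
  ridx <- c(1:(h1 + 1), if (h1 + 2 <= n1) (N1 - (n1 - h1 - 2)):N1)
  cidx <- c(1:(h2 + 1), if (h2 + 2 <= n2) (N2 - (n2 - h2 - 2)):N2)
  big[ridx, cidx] <- resp_f
  r <- Re(fft(big, inverse = TRUE)) / (n1 * n2)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  dy <- (pk[1] - 1) / U; dx <- (pk[2] - 1) / U
  if (dy > n1 / 2) dy <- dy - n1
  if (dx > n2 / 2) dx <- dx - n2
  c(dy, dx, max(r))
}

#' Online KCF template update
#'
#' Retrains on the new window-sized patch and linearly interpolates the
#' template and dual coefficients: `new = (1 - eta) * old + eta * fresh`.
#'
#' @param model A `kcf_model`.
#' @param patch Window-sized image patch at the current target position.
#' @param eta Learning rate in \[0, 1\] (default from the model's params).
#' @return Updated `kcf_model`.
#' @export
kcf_update <- function(model, patch, eta = model$params$eta) {
  stopifnot(eta >= 0, eta <= 1)
  if (eta == 0) return(model)
  fresh <- kcf_fit_window(model, to_gray(patch))
  if (eta == 1) return(fresh)
  model$xf <- Map(function(old, new) (1 - eta) * old + eta * new, model$xf, fresh$xf)
  model$alphaf <- (1 - eta) * model$alphaf + eta * fresh$alphaf
  model
}
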