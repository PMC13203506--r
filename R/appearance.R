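# Appearance pipeline for re-identification: adaptive resize preprocessing,
# a deterministic weight-free reference feature extractor, cosine distances
# and a bounded per-track feature gallery. The extractor contract is
# pluggable: any function (patch) -> L2-normalized numeric vector of constant
# length can replace the reference implementation in the tracker config.

#' Adaptive resize of an image patch
#'
#' If both the height and width of the patch are at least `predefined`, the
#' patch is returned unchanged; otherwise it is smoothly resized with
#' bilinear interpolation so that both sides equal `predefined` (a fixed
#' square shape, as required for downstream tensorization).
#'
#' @param patch Matrix (grayscale) or h x w x c array.
#' @param predefined Target side length in pixels (default 128).
#' @return The patch, unchanged or resized to `predefined` x `predefined`.
#' @export
adaptive_resize <- function(patch, predefined = 128L) {
  if (predefined <= 0) stop("predefined size must be positive", call. = FALSE)
  d <- dim(patch)
  if (is.null(d) || d[1] == 0 || d[2] == 0) stop("empty patch", call. = FALSE)
  if (d[1] >= predefined && d[2] >= predefined) return(patch)
  resize_bilinear(patch, predefined, predefined)
}

#' Reference appearance feature extractor
#'
#' Deterministic, weight-free stand-in for a trained re-identification
#' embedding: a coarse intensity/color histogram concatenated with a
#' gradient-orientation histogram, L2-normalized. Grayscale patches use 16
#' intensity bins; 3-channel patches use a 4 x 4 x 4 joint color histogram.
#'
#' @param patch Matrix or h x w x 3 array with values in \[0, 255\].
#' @return Unit-norm numeric `feature` vector (length 25 grayscale / 73 color).
#' @export
extract_features <- function(patch) {
  d <- dim(patch)
  if (is.null(d) || d[1] == 0 || d[2] == 0) stop("empty patch", call. = FALSE)
  if (length(d) == 3 && d[3] >= 3) {
    q <- function(ch) pmin(pmax(floor(ch / 64), 0), 3)
    idx <- q(patch[, , 1]) + 4 * q(patch[, , 2]) + 16 * q(patch[, , 3])
    colhist <- tabulate(idx + 1, nbins = 64)
    gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  } else {
    if (length(d) == 3) patch <- patch[, , 1]
    colhist <- tabulate(pmin(pmax(floor(patch / 16), 0), 15) + 1, nbins = 16)
    gray <- patch
  }
  h <- nrow(gray); w <- ncol(gray)
  if (h >= 3 && w >= 3) {
    gx <- (gray[, c(2:w, w)] - gray[, c(1, 1:(w - 1))]) / 2
    gy <- (gray[c(2:h, h), ] - gray[c(1, 1:(h - 1)), ]) / 2
    mag <- sqrt(gx^2 + gy^2)
    ang <- atan2(gy, gx) %% pi
    bin <- pmin(floor(ang / pi * 9), 8)
    ghist <- vapply(0:8, function(b) sum(mag[bin == b]), 0)
  } else {
    ghist <- numeric(9)
  }
  v <- c(colhist / max(1, length(gray)), ghist / max(1, sum(ghist)))
  n <- sqrt(sum(v^2))
  if (n == 0) v[1] <- 1 else v <- v / n
  v
}

#' Cosine distance between two normalized feature vectors
#'
#' @param f1,f2 Unit-norm numeric vectors of equal length.
#' @return `1 - dot(f1, f2)`, in \[0, 2\].
#' @export
cosine_distance <- function(f1, f2) {
  1 - sum(f1 * f2)
}

#' Bounded appearance gallery
#'
#' A per-track queue of the most recent feature vectors: when the budget is
#' exceeded the oldest entry is evicted first.
#'
#' @param gallery List of feature vectors (possibly empty).
#' @param f Feature vector to append.
#' @param budget Maximum number of stored vectors (default 100).
#' @return Updated list.
#' @export
gallery_add <- function(gallery, f, budget = 100L) {
  gallery <- c(gallery, list(f))
  if (length(gallery) > budget) gallery <- gallery[(length(gallery) - budget + 1):length(gallery)]
  gallery
}

#' Minimum cosine distance from a feature to a gallery
#'
#' @param gallery Non-empty list of stored feature vectors.
#' @param f Query feature vector.
#' @return Smallest [cosine_distance()] between `f` and any stored vector.
#' @export
gallery_distance <- function(gallery, f) {
  if (length(gallery) == 0) stop("empty gallery has no features", call. = FALSE)
  G <- do.call(rbind, gallery)
  min(1 - drop(G %*% f))
}
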