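# Bounding-box algebra. Boxes are continuous corner quadruples
# (x_min, y_min, x_max, y_max), origin top-left, x right, y down; area uses
# open-interval width (no +1) so the overlap algebra is exact.

#' Construct a bounding box
#'
#' @param x_min,y_min,x_max,y_max Real pixel coordinates, origin top-left.
#' @return Named numeric vector of length 4.
#' @examples
#' bbox(0, 0, 2, 2)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  if (x_max < x_min || y_max < y_min) {
    stop("invalid box: x_max >= x_min and y_max >= y_min required", call. = FALSE)
  }
  c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
}

#' Box area
#' @param b Box as returned by [bbox()] (any numeric length-4 vector).
#' @return Non-negative area.
#' @export
box_area <- function(b) {
  max(0, b[[3]] - b[[1]]) * max(0, b[[4]] - b[[2]])
}

#' Intersection over Union of two boxes
#'
#' Overlap area divided by union area. Degenerate (zero-area) inputs give 0;
#' identical non-degenerate boxes give 1.
#'
#' @param b1,b2 Boxes (length-4 corner vectors).
#' @return IoU in \[0, 1\].
#' @examples
#' box_iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3)) # 1/7
#' @export
box_iou <- function(b1, b2) {
  iw <- max(0, min(b1[[3]], b2[[3]]) - max(b1[[1]], b2[[1]]))
  ih <- max(0, min(b1[[4]], b2[[4]]) - max(b1[[2]], b2[[2]]))
  inter <- iw * ih
  un <- box_area(b1) + box_area(b2) - inter
  if (un <= 0) return(0)
  inter / un
}

# IoU of every row of A against every row of B (n x 4, m x 4 corner matrices).
iou_matrix <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  n <- nrow(A); m <- nrow(B)
  iw <- pmax(0, outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax))
  ih <- pmax(0, outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax))
  inter <- iw * ih
  areaA <- pmax(0, A[, 3] - A[, 1]) * pmax(0, A[, 4] - A[, 2])
  areaB <- pmax(0, B[, 3] - B[, 1]) * pmax(0, B[, 4] - B[, 2])
  un <- outer(areaA, areaB, `+`) - inter
  out <- matrix(0, n, m)
  pos <- un > 0
  out[pos] <- inter[pos] / un[pos]
  out
}

#' Complete-IoU (CIoU) loss between a predicted and a ground-truth box
#'
#' \deqn{L = 1 - IoU + \rho^2/c^2 + \alpha v} with \eqn{\rho} the distance
#' between box centers, \eqn{c} the diagonal of the smallest enclosing box,
#' \eqn{v = (4/\pi^2)(\arctan(w_{gt}/h_{gt}) - \arctan(w/h))^2} the
#' aspect-ratio consistency term and \eqn{\alpha = v/((1 - IoU) + v)}.
#'
#' @param pred,gt Boxes (length-4 corner vectors); `gt` must be non-degenerate.
#' @return Loss value (>= 0 for overlapping-geometry inputs; equals 0 when
#'   `pred == gt`).
#' @examples
#' ciou_loss(bbox(0, 0, 2, 2), bbox(2, 0, 4, 2)) # 1.2
#' @export
ciou_loss <- function(pred, gt) {
  if (box_area(gt) <= 0) stop("ground-truth box is degenerate", call. = FALSE)
  w <- pred[[3]] - pred[[1]]; h <- pred[[4]] - pred[[2]]
  wg <- gt[[3]] - gt[[1]]; hg <- gt[[4]] - gt[[2]]
  if (h <= 0 || hg <= 0) stop("zero-height box: aspect ratio undefined", call. = FALSE)
  iou <- box_iou(pred, gt)
  cx <- (pred[[1]] + pred[[3]]) / 2; cy <- (pred[[2]] + pred[[4]]) / 2
  gx <- (gt[[1]] + gt[[3]]) / 2; gy <- (gt[[2]] + gt[[4]]) / 2
  rho2 <- (cx - gx)^2 + (cy - gy)^2
  cw <- max(pred[[3]], gt[[3]]) - min(pred[[1]], gt[[1]])
  ch <- max(pred[[4]], gt[[4]]) - min(pred[[2]], gt[[2]])
  c2 <- cw^2 + ch^2
  v <- 4 / pi^2 * (atan(wg / hg) - atan(w / h))^2
  alpha <- if (v == 0) 0 else v / ((1 - iou) + v)
  1 - iou + rho2 / c2 + alpha * v
}

#' Non-maximum suppression
#'
#' Greedy descending-confidence suppression: detections below
#' `conf_threshold` are dropped, then boxes are visited in order of
#' decreasing confidence and any remaining box with IoU strictly greater than
#' `iou_threshold` against an already-kept box is suppressed. Confidence ties
#' are broken by original row order, so output is deterministic.
#'
#' @param detections Data frame with columns `x`, `y`, `w`, `h`
#'   (left/top/width/height) and `conf` in \[0, 1\].
#' @param iou_threshold Suppression threshold (default 0.4).
#' @param conf_threshold Minimum confidence kept (default 0.25).
#' @return Tibble: the surviving rows of `detections`, original order of
#'   selection (descending confidence).
#' @examples
#' d <- tibble::tibble(x = c(0, 1, 50), y = 0, w = 10, h = 10,
#'                     conf = c(0.9, 0.8, 0.7))
#' nms(d)
#' @export
nms <- function(detections, iou_threshold = 0.4, conf_threshold = 0.25) {
  stopifnot(all(c("x", "y", "w", "h", "conf") %in% names(detections)))
  d <- tibble::as_tibble(detections)
  d <- d[d$conf >= conf_threshold, , drop = FALSE]
  if (nrow(d) == 0) return(d)
  ord <- order(-d$conf, seq_len(nrow(d)))
  d <- d[ord, , drop = FALSE]
  boxes <- cbind(d$x, d$y, d$x + d$w, d$y + d$h)
  keep <- logical(nrow(d))
  alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(d)) {
      rest <- which(alive & seq_len(nrow(d)) > i)
      if (length(rest)) {
        ious <- iou_matrix(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])
        alive[rest[ious[1, ] > iou_threshold]] <- FALSE
      }
    }
  }
  d[keep, , drop = FALSE]
}

#' Letterbox resize
#'
#' Aspect-preserving resize of an image to a `target` x `target` square, with
#' the remainder padded by a constant value (mid-gray 114 by default). When
#' total padding on an axis is odd the extra pixel goes to the bottom/right.
#' The returned `scale` and `offset` invert the mapping exactly:
#' `original = (letterboxed - offset) / scale`.
#'
#' @param image Matrix (grayscale, rows = y) or h x w x c array.
#' @param target Output side length in pixels (default 640).
#' @param pad_value Padding intensity (default 114).
#' @return List with `image` (target x target), `scale`, `offset_x`,
#'   `offset_y` (padding left / top in output pixels).
#' @export
letterbox <- function(image, target = 640L, pad_value = 114) {
  if (target <= 0) stop("letterbox target must be positive", call. = FALSE)
  d <- dim(image)
  if (is.null(d) || d[1] == 0 || d[2] == 0) stop("empty image", call. = FALSE)
  h <- d[1]; w <- d[2]
  nc <- if (length(d) == 3) d[3] else 1L
  s <- min(target / w, target / h)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  resized <- resize_bilinear(image, nh, nw)
  pad_y <- target - nh; pad_x <- target - nw
  top <- pad_y %/% 2L; left <- pad_x %/% 2L
  if (nc == 1L) {
    out <- matrix(pad_value, target, target)
    out[top + seq_len(nh), left + seq_len(nw)] <- resized
  } else {
    out <- array(pad_value, c(target, target, nc))
    out[top + seq_len(nh), left + seq_len(nw), ] <- resized
  }
  list(image = out, scale = s, offset_x = left, offset_y = top)
}

#' Map coordinates through / out of a letterbox transform
#'
#' @param xy Two-column matrix (or length-2 vector) of (x, y) coordinates.
#' @param lb Result of [letterbox()].
#' @return Transformed coordinates, same shape as input.
#' @export
letterbox_coords <- function(xy, lb) {
  xy <- rbind(xy)
  cbind(xy[, 1] * lb$scale + lb$offset_x, xy[, 2] * lb$scale + lb$offset_y)
}

#' @rdname letterbox_coords
#' @export
letterbox_coords_inv <- function(xy, lb) {
  xy <- rbind(xy)
  cbind((xy[, 1] - lb$offset_x) / lb$scale, (xy[, 2] - lb$offset_y) / lb$scale)
}

# bilinear resize of a matrix or h x w x c array via EBImage; our images are
# (row = y, col = x) so EBImage's first dimension argument receives the height
resize_bilinear <- function(image, new_h, new_w) {
  d <- dim(image)
  if (d[1] == new_h && d[2] == new_w) return(image)
  out <- EBImage::resize(image, w = new_h, h = new_w)
  if (is.array(out) && length(dim(out)) > length(d)) dim(out) <- dim(out)[seq_along(d)]
  out
}

# conversions between MOT left/top/width/height rows and corner matrices
ltwh_to_corners <- function(df) {
  cbind(df$x, df$y, df$x + df$w, df$y + df$h, deparse.level = 0)
}

corners_to_ltwh <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  tibble::tibble(x = m[, 1], y = m[, 2], w = m[, 3] - m[, 1], h = m[, 4] - m[, 2])
}
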