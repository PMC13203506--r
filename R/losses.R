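# Detection-loss formula library: binary cross-entropy for classification
# and objectness, and the weighted composite loss. The box-regression term
# (CIoU) lives with the box algebra as ciou_loss(). Verifiable formulas only
# (the tracker consumes detections; no training loop).

#' Loss weighting coefficients
#'
#' Defaults follow the standard single-stage detector configuration:
#' classification 0.5, box regression 7.5, objectness 1.0.
#'
#' @param cls,box,obj Non-negative weights.
#' @return Named numeric vector.
#' @export
loss_weights <- function(cls = 0.5, box = 7.5, obj = 1.0) {
  w <- c(cls = cls, box = box, obj = obj)
  if (any(w < 0)) stop("loss weights must be non-negative", call. = FALSE)
  w
}

#' Binary cross-entropy
#'
#' \deqn{-\frac1N \sum_i [y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i)]}
#' Predictions are clipped to `[eps, 1 - eps]` to keep the logarithms finite.
#'
#' @param y Labels in \{0, 1\}.
#' @param p Predicted probabilities, same length as `y`.
#' @param eps Clipping constant (default 1e-7).
#' @return Mean BCE, >= 0.
#' @examples
#' bce_loss(1, 0.5) # log(2)
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  if (length(y) == 0) stop("empty input to bce_loss", call. = FALSE)
  if (length(y) != length(p)) stop("label/prediction length mismatch", call. = FALSE)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Objectness loss over grid cells
#'
#' BCE between per-cell object indicators and predicted objectness
#' probabilities; identical contract to [bce_loss()].
#'
#' @param o Grid-cell object indicators in \{0, 1\}.
#' @param p Predicted objectness probabilities.
#' @param eps Clipping constant.
#' @return Mean BCE.
#' @export
objectness_loss <- function(o, p, eps = 1e-7) {
  bce_loss(o, p, eps)
}

#' Composite detection loss
#'
#' Weighted sum of the classification, box-regression and objectness
#' components: `w["cls"] * l_cls + w["box"] * l_box + w["obj"] * l_obj`.
#'
#' @param l_cls,l_box,l_obj Non-negative component losses.
#' @param weights [loss_weights()].
#' @return Total loss.
#' @examples
#' total_loss(1, 1, 1) # 9
#' @export
total_loss <- function(l_cls, l_box, l_obj, weights = loss_weights()) {
  stopifnot(l_cls >= 0, l_box >= 0, l_obj >= 0)
  unname(weights[["cls"]] * l_cls + weights[["box"]] * l_box + weights[["obj"]] * l_obj)
}
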