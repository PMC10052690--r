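#' Intersection-over-union of two masks
#'
#' \eqn{|pred \cap truth| / |pred \cup truth|}; defined as 1 when both masks
#' are empty.
#'
#' @param pred,truth logical mask matrices of identical dimensions.
#' @return a number in `[0, 1]`.
#' @export
mask_iou <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (!all(dim(pred) == dim(truth))) {
    abort_bs("masks must have identical dimensions", "usage_error")
  }
  u <- sum(pred | truth)
  if (u == 0L) return(1)
  sum(pred & truth) / u
}

#' Pixel-level confusion counts and derived scores
#'
#' Returns true/false positive/negative pixel counts plus the
#' intersection-over-union, Matthews correlation coefficient
#' \deqn{mcc = (tp \cdot tn - fp \cdot fn) /
#'   \sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)},}
#' (0 when any denominator factor is 0), false-positive rate
#' `fp / (fp + tn)` and false-negative rate `fn / (fn + tp)` (each 0 when its
#' denominator is 0).
#'
#' @param pred,truth logical mask matrices of identical dimensions.
#' @return an object of class `mask_comparison`: a list with `tp`, `fp`,
#'   `fn`, `tn`, `iou`, `mcc`, `fp_rate`, `fn_rate`.
#' @export
mask_confusion <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (!all(dim(pred) == dim(truth))) {
    abort_bs("masks must have identical dimensions", "usage_error")
  }
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  u <- tp + fp + fn
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    iou = if (u == 0L) 1 else tp / u,
    mcc = mcc,
    fp_rate = if (fp + tn == 0L) 0 else fp / (fp + tn),
    fn_rate = if (fn + tp == 0L) 0 else fn / (fn + tp)
  ), class = "mask_comparison")
}

#' @export
print.mask_comparison <- function(x, ...) {
  cat(sprintf("<mask_comparison> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  iou=%.4f mcc=%.4f fp_rate=%.4f fn_rate=%.4f\n",
              x$iou, x$mcc, x$fp_rate, x$fn_rate))
  invisible(x)
}

#' Symmetric Hausdorff distance between two contours
#'
#' Maximum over both directions of the nearest-neighbour Euclidean distance
#' between the two point sets, in pixels, at whatever sampling density the
#' contours carry.
#'
#' @param a,b contour matrices (columns x, y), both nonempty.
#' @return the Hausdorff distance in pixels.
#' @export
hausdorff_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    abort_bs("contours must be nonempty", "metric_error")
  }
  pracma::hausdorff_dist(a[, 1:2, drop = FALSE], b[, 1:2, drop = FALSE])
}
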