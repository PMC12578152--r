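#' Shape-IoU loss parameters
#'
#' `scale` is a dataset-level scale factor controlling how strongly the
#' ground-truth aspect ratio weights the two image axes; `scale = 0` makes
#' both weights 1 so the loss reduces to IoU plus an unweighted normalized
#' center distance plus the shape term. `theta` sharpens the shape
#' discrepancy term (default 4).
#'
#' @param scale Non-negative scale factor (default 0).
#' @param theta Positive exponent of the shape term (default 4).
#' @return A list of class `shape_iou_params`.
#' @export
shape_iou_params <- function(scale = 0, theta = 4) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale >= 0,
            is.numeric(theta), length(theta) == 1L, theta > 0)
  structure(list(scale = scale, theta = theta), class = "shape_iou_params")
}

#' Axis weights derived from the ground-truth box shape
#'
#' The horizontal weight grows with the ground-truth width relative to its
#' height (and vice versa), normalized so the two weights always sum to 2:
#' `ww = 2 (w_gt)^scale / ((w_gt)^scale + (h_gt)^scale)` and symmetrically
#' for `hh`. With `scale = 0` or a square ground truth both are 1.
#'
#' @param gt Ground-truth box.
#' @param scale Non-negative scale factor.
#' @return Named numeric vector `c(ww =, hh =)`.
#' @export
shape_weights <- function(gt, scale = 0) {
  gt <- as_box(gt)
  stopifnot(scale >= 0)
  ws <- gt[["w"]]^scale
  hs <- gt[["h"]]^scale
  c(ww = 2 * ws / (ws + hs), hh = 2 * hs / (ws + hs))
}

# Diagonal length^2 of the smallest axis-aligned box enclosing both boxes.
enclosing_diag2 <- function(a, b) {
  cw <- max(a[["cx"]] + a[["w"]] / 2, b[["cx"]] + b[["w"]] / 2) -
        min(a[["cx"]] - a[["w"]] / 2, b[["cx"]] - b[["w"]] / 2)
  ch <- max(a[["cy"]] + a[["h"]] / 2, b[["cy"]] + b[["h"]] / 2) -
        min(a[["cy"]] - a[["h"]] / 2, b[["cy"]] - b[["h"]] / 2)
  cw^2 + ch^2
}

#' Shape-weighted normalized center distance
#'
#' The squared center offsets along x and y, each normalized by the diagonal
#' of the minimal box enclosing the pair and weighted by the shape weight of
#' the *other* axis: `hh * (dx/c)^2 + ww * (dy/c)^2`. Zero iff the centers
#' coincide; invariant under joint translation of both boxes.
#'
#' @param pred,gt Predicted and ground-truth boxes.
#' @param scale Non-negative scale factor.
#' @return Non-negative scalar.
#' @export
shape_distance <- function(pred, gt, scale = 0) {
  pred <- as_box(pred); gt <- as_box(gt)
  w <- shape_weights(gt, scale)
  c2 <- enclosing_diag2(pred, gt)
  dx2 <- (pred[["cx"]] - gt[["cx"]])^2
  dy2 <- (pred[["cy"]] - gt[["cy"]])^2
  unname(w[["hh"]] * dx2 / c2 + w[["ww"]] * dy2 / c2)
}

#' Shape discrepancy term
#'
#' Relative width and height mismatches, cross-weighted by the ground-truth
#' shape weights and squashed through `(1 - exp(-omega))^theta`:
#' `omega_w = hh |w - w_gt| / max(w, w_gt)`,
#' `omega_h = ww |h - h_gt| / max(h, h_gt)`,
#' `Omega = sum_t (1 - exp(-omega_t))^theta`. Zero iff the two boxes have
#' identical width and height; each summand lies in `[0, 1)`.
#'
#' @param pred,gt Predicted and ground-truth boxes.
#' @param scale Non-negative scale factor.
#' @param theta Positive exponent (default 4).
#' @return Non-negative scalar.
#' @export
shape_omega <- function(pred, gt, scale = 0, theta = 4) {
  pred <- as_box(pred); gt <- as_box(gt)
  stopifnot(theta > 0)
  w <- shape_weights(gt, scale)
  omega_w <- w[["hh"]] * abs(pred[["w"]] - gt[["w"]]) / max(pred[["w"]], gt[["w"]])
  omega_h <- w[["ww"]] * abs(pred[["h"]] - gt[["h"]]) / max(pred[["h"]], gt[["h"]])
  (1 - exp(-omega_w))^theta + (1 - exp(-omega_h))^theta
}

#' Shape-IoU bounding-box regression loss
#'
#' `loss = 1 - IoU + distance_shape + Omega_shape / 2`, combining overlap,
#' a shape-weighted normalized center distance ([shape_distance()]) and a
#' shape discrepancy term ([shape_omega()]). The loss is zero iff the
#' predicted and ground-truth boxes are identical.
#'
#' @param pred,gt Predicted and ground-truth boxes.
#' @param params A [shape_iou_params()] object.
#' @return A list of class `shape_iou_breakdown` with elements `iou`,
#'   `distance_shape`, `omega_shape`, `ww`, `hh` and `loss`. The identity
#'   `loss = 1 - iou + distance_shape + omega_shape/2` holds exactly.
#' @examples
#' shape_iou_loss(box(1, 0, 2, 2), box(0, 0, 2, 2))$loss
#' @export
shape_iou_loss <- function(pred, gt, params = shape_iou_params()) {
  pred <- as_box(pred); gt <- as_box(gt)
  w <- shape_weights(gt, params$scale)
  iou <- box_iou(pred, gt)
  d <- shape_distance(pred, gt, params$scale)
  om <- shape_omega(pred, gt, params$scale, params$theta)
  structure(list(iou = iou, distance_shape = d, omega_shape = om,
                 ww = unname(w[["ww"]]), hh = unname(w[["hh"]]),
                 loss = 1 - iou + d + om / 2),
            class = "shape_iou_breakdown")
}

#' @export
print.shape_iou_breakdown <- function(x, ...) {
  cat(sprintf(
    "Shape-IoU: loss %.6f (IoU %.6f, dist %.6f, omega %.6f; ww %.4f hh %.4f)\n",
    x$loss, x$iou, x$distance_shape, x$omega_shape, x$ww, x$hh))
  invisible(x)
}

#' DIoU and CIoU comparison losses
#'
#' Plain distance-IoU and complete-IoU losses, provided as untuned baselines
#' for comparing against the Shape-IoU loss; both use the same enclosing-box
#' diagonal normalization.
#'
#' @param pred,gt Predicted and ground-truth boxes.
#' @return Scalar loss value.
#' @export
diou_loss <- function(pred, gt) {
  pred <- as_box(pred); gt <- as_box(gt)
  d2 <- (pred[["cx"]] - gt[["cx"]])^2 + (pred[["cy"]] - gt[["cy"]])^2
  1 - box_iou(pred, gt) + d2 / enclosing_diag2(pred, gt)
}

#' @rdname diou_loss
#' @export
ciou_loss <- function(pred, gt) {
  pred <- as_box(pred); gt <- as_box(gt)
  iou <- box_iou(pred, gt)
  d2 <- (pred[["cx"]] - gt[["cx"]])^2 + (pred[["cy"]] - gt[["cy"]])^2
  v <- 4 / pi^2 * (atan(gt[["w"]] / gt[["h"]]) - atan(pred[["w"]] / pred[["h"]]))^2
  alpha <- if (iou < 0.5 || v == 0) 0 else v / (1 - iou + v)
  1 - iou + d2 / enclosing_diag2(pred, gt) + alpha * v
}
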