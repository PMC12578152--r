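#' Axis-aligned bounding box in center parameterization
#'
#' Boxes are continuous pixel coordinates with the image origin at the top
#' left and y increasing downward. The center form `(cx, cy, w, h)` is the
#' operand of all geometry operations; converters to and from top-left and
#' corner forms are provided by [convert_box()].
#'
#' @param cx,cy Center coordinates in pixels.
#' @param w,h Width and height in pixels; must be strictly positive.
#' @return A named numeric vector of class `box` with elements
#'   `cx`, `cy`, `w`, `h`.
#' @examples
#' b <- box(10, 20, 4, 8)
#' box_iou(b, box(12, 20, 4, 8))
#' @export
box <- function(cx, cy, w, h) {
  b <- c(cx = as.numeric(cx), cy = as.numeric(cy),
         w = as.numeric(w), h = as.numeric(h))
  validate_box(b)
  class(b) <- "box"
  b
}

#' Validate a box
#'
#' Rejects non-finite coordinates and non-positive width or height.
#' Degenerate boxes are rejected rather than clamped: silent clamping would
#' mask upstream bugs (for example in a simulator or a detector adapter).
#'
#' @param b Numeric vector `(cx, cy, w, h)`.
#' @return `b`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_box <- function(b) {
  if (length(b) != 4L || !is.numeric(b)) {
    stop("a box must be a numeric vector (cx, cy, w, h)", call. = FALSE)
  }
  if (!all(is.finite(b))) {
    stop("box coordinates must be finite", call. = FALSE)
  }
  if (b[[3L]] <= 0 || b[[4L]] <= 0) {
    stop("box width and height must be strictly positive (got w=",
         b[[3L]], ", h=", b[[4L]], ")", call. = FALSE)
  }
  invisible(b)
}

as_box <- function(b) {
  if (inherits(b, "box")) return(b)
  box(b[[1L]], b[[2L]], b[[3L]], b[[4L]])
}

#' @export
print.box <- function(x, ...) {
  cat(sprintf("box: center (%.6g, %.6g), %g x %g px\n",
              x[["cx"]], x[["cy"]], x[["w"]], x[["h"]]))
  invisible(x)
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes in center form (see [box()]).
#' @return IoU in `[0, 1]`; 0 for disjoint boxes, 1 iff `a == b`.
#' @export
box_iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ix <- pmin(a[["cx"]] + a[["w"]] / 2, b[["cx"]] + b[["w"]] / 2) -
        pmax(a[["cx"]] - a[["w"]] / 2, b[["cx"]] - b[["w"]] / 2)
  iy <- pmin(a[["cy"]] + a[["h"]] / 2, b[["cy"]] + b[["h"]] / 2) -
        pmax(a[["cy"]] - a[["h"]] / 2, b[["cy"]] - b[["h"]] / 2)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[["w"]] * a[["h"]] + b[["w"]] * b[["h"]] - inter)
}

#' IoU matrix between two sets of boxes
#'
#' Vectorized pairwise IoU used by the tracker's association stages and the
#' evaluation protocol.
#'
#' @param A,B Matrices or data.frames with columns `cx, cy, w, h`
#'   (one box per row).
#' @return `nrow(A)` x `nrow(B)` matrix of IoU values.
#' @export
box_iou_matrix <- function(A, B) {
  A <- box_mat(A); B <- box_mat(B)
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  ax1 <- A[, 1L] - A[, 3L] / 2; ax2 <- A[, 1L] + A[, 3L] / 2
  ay1 <- A[, 2L] - A[, 4L] / 2; ay2 <- A[, 2L] + A[, 4L] / 2
  bx1 <- B[, 1L] - B[, 3L] / 2; bx2 <- B[, 1L] + B[, 3L] / 2
  by1 <- B[, 2L] - B[, 4L] / 2; by2 <- B[, 2L] + B[, 4L] / 2
  ix <- pmax(outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax), 0)
  iy <- pmax(outer(ay2, by2, pmin) - outer(ay1, by1, pmax), 0)
  inter <- ix * iy
  areas <- outer(A[, 3L] * A[, 4L], B[, 3L] * B[, 4L], `+`)
  iou <- inter / (areas - inter)
  iou[!is.finite(iou)] <- 0
  iou
}

box_mat <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("cx", "cy", "w", "h")])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}

#' Convert between box conventions
#'
#' Supported conventions: `"center"` (cx, cy, w, h), `"tlwh"` (top-left x,
#' top-left y, w, h), `"corners"` (x1, y1, x2, y2) and `"yolo"`
#' (normalized cx, cy, w, h in `[0,1]`, requiring `img_w`/`img_h`).
#' Round trips are exact to floating point.
#'
#' @param b Numeric length-4 vector in the `from` convention.
#' @param from,to Convention names.
#' @param img_w,img_h Image dimensions in pixels, required whenever
#'   `"yolo"` is involved.
#' @return Numeric length-4 vector in the `to` convention (a `box` object
#'   when `to = "center"`).
#' @export
convert_box <- function(b, from, to, img_w = NULL, img_h = NULL) {
  conventions <- c("center", "tlwh", "corners", "yolo")
  from <- match.arg(from, conventions)
  to <- match.arg(to, conventions)
  b <- as.numeric(b)
  if (length(b) != 4L) stop("expected a length-4 box", call. = FALSE)
  needs_img <- "yolo" %in% c(from, to)
  if (needs_img && (is.null(img_w) || is.null(img_h))) {
    stop("img_w and img_h are required for YOLO-normalized conversions",
         call. = FALSE)
  }
  ctr <- switch(from,
    center  = b,
    tlwh    = c(b[1L] + b[3L] / 2, b[2L] + b[4L] / 2, b[3L], b[4L]),
    corners = c((b[1L] + b[3L]) / 2, (b[2L] + b[4L]) / 2,
                b[3L] - b[1L], b[4L] - b[2L]),
    yolo    = c(b[1L] * img_w, b[2L] * img_h, b[3L] * img_w, b[4L] * img_h))
  out <- switch(to,
    center  = ctr,
    tlwh    = c(ctr[1L] - ctr[3L] / 2, ctr[2L] - ctr[4L] / 2, ctr[3L], ctr[4L]),
    corners = c(ctr[1L] - ctr[3L] / 2, ctr[2L] - ctr[4L] / 2,
                ctr[1L] + ctr[3L] / 2, ctr[2L] + ctr[4L] / 2),
    yolo    = c(ctr[1L] / img_w, ctr[2L] / img_h, ctr[3L] / img_w, ctr[4L] / img_h))
  if (to == "center") box(out[1L], out[2L], out[3L], out[4L]) else unname(out)
}
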