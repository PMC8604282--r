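#' Bounding-box utilities
#'
#' Boxes throughout the package are axis-aligned pixel rectangles in the
#' half-open convention `[x1, x2) x [y1, y2)`, 0-based, so `x2 - x1` is the
#' width in pixels. Pascal VOC's 1-based inclusive convention is converted at
#' the XML boundary only (see [read_voc_annotations()]).
#'
#' @param boxes,a,b numeric matrices with columns `x1, y1, x2, y2` (one row
#'   per box), or length-4 vectors for single boxes.
#' @name boxes
NULL

as_box_matrix <- function(boxes) {
  if (is.null(boxes) || length(boxes) == 0L) {
    return(matrix(numeric(0), 0, 4, dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  }
  if (is.data.frame(boxes)) boxes <- as.matrix(boxes[, c("x1", "y1", "x2", "y2")])
  if (!is.matrix(boxes)) boxes <- matrix(boxes, ncol = 4, byrow = TRUE)
  colnames(boxes) <- c("x1", "y1", "x2", "y2")
  boxes
}

box_area <- function(boxes) {
  boxes <- as_box_matrix(boxes)
  pmax(0, boxes[, 3] - boxes[, 1]) * pmax(0, boxes[, 4] - boxes[, 2])
}

#' Pairwise intersection-over-union between two box sets
#'
#' @param a,b box matrices (see [boxes]).
#' @return an `nrow(a)` by `nrow(b)` matrix of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(numeric(0), na, nb))
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  un <- outer(box_area(a), box_area(b), `+`) - inter
  out <- inter / un
  out[un == 0] <- 0
  out
}

clip_boxes <- function(boxes, width, height) {
  boxes <- as_box_matrix(boxes)
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), width)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), height)
  boxes
}

#' Anchor-relative box encoding
#'
#' Encodes a ground-truth box as dimensionless deviations
#' `t = ((x - xa)/wa, (y - ya)/ha, log(w/wa), log(h/ha))` from an anchor box,
#' where `(x, y, w, h)` are centre coordinates and side lengths. `decode` is
#' the exact inverse, so `decode(encode(b, a), a) == b`.
#'
#' @param gt_box,anchor,deltas box matrices / delta matrices (rows aligned).
#' @return a matrix of deltas (`encode_box_deltas`) or corner-format boxes
#'   (`decode_box_deltas`).
#' @export
encode_box_deltas <- function(gt_box, anchor) {
  g <- as_box_matrix(gt_box); a <- as_box_matrix(anchor)
  gw <- g[, 3] - g[, 1]; gh <- g[, 4] - g[, 2]
  aw <- a[, 3] - a[, 1]; ah <- a[, 4] - a[, 2]
  if (any(gw <= 0 | gh <= 0 | aw <= 0 | ah <= 0)) {
    stop("encode_box_deltas(): boxes and anchors must have positive extent")
  }
  gx <- (g[, 1] + g[, 3]) / 2; gy <- (g[, 2] + g[, 4]) / 2
  ax <- (a[, 1] + a[, 3]) / 2; ay <- (a[, 2] + a[, 4]) / 2
  cbind(tx = (gx - ax) / aw, ty = (gy - ay) / ah,
        tw = log(gw / aw), th = log(gh / ah))
}

#' @rdname encode_box_deltas
#' @export
decode_box_deltas <- function(deltas, anchor) {
  d <- matrix(deltas, ncol = 4)
  a <- as_box_matrix(anchor)
  aw <- a[, 3] - a[, 1]; ah <- a[, 4] - a[, 2]
  if (any(aw <= 0 | ah <= 0)) stop("decode_box_deltas(): anchors must have positive extent")
  ax <- (a[, 1] + a[, 3]) / 2; ay <- (a[, 2] + a[, 4]) / 2
  x <- d[, 1] * aw + ax; y <- d[, 2] * ah + ay
  w <- exp(d[, 3]) * aw; h <- exp(d[, 4]) * ah
  cbind(x1 = x - w / 2, y1 = y - h / 2, x2 = x + w / 2, y2 = y + h / 2)
}

#' Smooth L1 (Huber) loss branch function
#'
#' `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise; continuous with continuous
#' first derivative at `|x| = 1`. Vectorised.
#'
#' @param x numeric vector.
#' @export
smooth_l1 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, 0.5 * x^2, ax - 0.5)
}

smooth_l1_grad <- function(x) {
  ifelse(abs(x) < 1, x, sign(x))
}

#' Greedy non-maximum suppression
#'
#' Standard greedy NMS: boxes are visited in descending score order; a box is
#' suppressed if its IoU with an already-kept box exceeds `iou_threshold`.
#'
#' @param boxes box matrix.
#' @param scores numeric vector, one score per box.
#' @param iou_threshold suppression threshold (default 0.7, the proposal-stage
#'   value used during training).
#' @return integer indices (into the input) of the kept boxes, in descending
#'   score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.7) {
  boxes <- as_box_matrix(boxes)
  n <- nrow(boxes)
  if (n == 0L) return(integer(0))
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  iou <- box_iou(boxes, boxes)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[iou[i, ] > iou_threshold] <- FALSE
  }
  keep
}
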