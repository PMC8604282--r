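# shared fixtures: small scenes are expensive enough to build once per run

small_scene <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7L, size = 96L, ...) {
    key <- paste(seed, size, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_scene(scene_config(image_size = size, seed = seed, ...))
    }
    cache[[key]]
  }
})

scene_rig <- function(size = 64L) {
  camera_rig(fx_depth = 1.2 * size, fy_depth = 1.2 * size,
             cx_depth = (size - 1) / 2, cy_depth = (size - 1) / 2)
}

# brute-force O(n^2) NMS reference: keep a box iff no higher-scored kept box
# overlaps it above the threshold
nms_reference <- function(boxes, scores, iou_threshold) {
  ord <- order(scores, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (box_iou(boxes[i, , drop = FALSE], boxes[j, , drop = FALSE])[1, 1] > iou_threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# independent AP oracle: all-point interpolation equals the mean over the
# n_gt recall levels of the best precision at recall >= k/n_gt
ap_oracle <- function(tp, n_gt) {
  if (!length(tp) || n_gt == 0) return(0)
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_gt
  mean(vapply(seq_len(n_gt), function(k) {
    ok <- rec >= k / n_gt - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))) * 100
}

random_boxes <- function(n, size = 100, min_side = 5, max_side = 40) {
  x1 <- stats::runif(n, 0, size - min_side)
  y1 <- stats::runif(n, 0, size - min_side)
  w <- stats::runif(n, min_side, max_side)
  h <- stats::runif(n, min_side, max_side)
  cbind(x1 = x1, y1 = y1, x2 = pmin(x1 + w, size), y2 = pmin(y1 + h, size))
}
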