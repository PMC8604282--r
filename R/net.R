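#' Three-branch multiscale RGB-D weed detection network
#'
#' The detector follows the two-stage region-proposal design: a five-block
#' convolutional backbone (stride-2 pooling after blocks 1-4, so block
#' outputs sit at strides 1, 2, 4, 8, 16 relative to the input) feeds three
#' detection branches:
#'
#' * an RGB-specific branch detecting from its block-5 feature map,
#' * a PHA-specific branch doing the same on the recoded depth image,
#' * a correlated branch detecting from the Hadamard (elementwise) product
#'   of the two branches' multiscale "hyper" features — block 1 max-pooled
#'   down, block 5 upsampled by a learned 4x transposed convolution, both to
#'   block-3 resolution (stride 4), channel-concatenated, RMS-normalised per
#'   channel and projected by a learned 1x1 convolution.
#'
#' Each branch has its own region proposal network (objectness + box deltas
#' over anchors, trained jointly with the same supervision) and RoI head
#' (7x7 max RoI pooling, two hidden layers, 3-way softmax over
#' grass/broadleaf/background and class-wise box regression). The RGB and
#' PHA backbones share weights by default.
#'
#' `variant = "vgg16"` builds the full-size backbone (64..512 channels, 13
#' conv layers); `variant = "tiny"` is a structurally identical reduced
#' backbone for CPU-scale experiments and tests.
#'
#' @param variant `"tiny"` or `"vgg16"`.
#' @param share_weights share backbone (and hyper-feature) parameters
#'   between the RGB and PHA branches.
#' @param anchor_scales anchor side lengths in input pixels.
#' @param anchor_ratios anchor aspect ratios (height/width).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `weednet`.
#' @export
weednet <- function(variant = c("tiny", "vgg16"), share_weights = TRUE,
                    anchor_scales = c(8, 16, 32), anchor_ratios = c(0.5, 1, 2),
                    seed = 1L) {
  variant <- match.arg(variant)
  cfg <- if (variant == "tiny") {
    list(channels = c(32, 48, 64, 64, 64), convs = c(1, 1, 1, 1, 1),
         hyper_c = 48L, rpn_mid = 64L, fc = 128L)
  } else {
    list(channels = c(64, 128, 256, 512, 512), convs = c(2, 2, 3, 3, 3),
         hyper_c = 126L, rpn_mid = 256L, fc = 512L)
  }
  cfg$variant <- variant
  cfg$share_weights <- share_weights
  cfg$anchor_scales <- anchor_scales
  cfg$anchor_ratios <- anchor_ratios
  cfg$classes <- weed_classes
  n_anchors <- length(anchor_scales) * length(anchor_ratios)

  counter <- new.env(); counter$i <- 0L
  mk <- function(dims, fan_in, zero = FALSE) {
    counter$i <- counter$i + 1L
    id <- paste0("p", counter$i)
    val <- if (zero) array(0, dims) else
      array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
    new_param(val, id)
  }
  conv_p <- function(cin, cout, k = 3L) {
    list(W = mk(c(k, k, cin, cout), k * k * cin), b = mk(cout, 1, zero = TRUE))
  }
  backbone_p <- function() {
    ch <- cfg$channels; cv <- cfg$convs
    blocks <- list()
    cin <- 3L
    for (b in 1:5) {
      layers <- list()
      for (l in seq_len(cv[b])) {
        layers[[l]] <- conv_p(cin, ch[b])
        cin <- ch[b]
      }
      blocks[[b]] <- layers
    }
    blocks
  }
  hyper_p <- function() {
    ch <- cfg$channels
    cat_c <- ch[1] + ch[3] + ch[5]
    list(deconv = list(W = mk(c(ch[5], 16 * ch[5]), ch[5]), b = mk(ch[5], 1, zero = TRUE)),
         proj = conv_p(cat_c, cfg$hyper_c, k = 1L))
  }
  rpn_p <- function(cin) {
    list(mid = conv_p(cin, cfg$rpn_mid),
         obj = conv_p(cfg$rpn_mid, n_anchors, k = 1L),
         reg = conv_p(cfg$rpn_mid, 4L * n_anchors, k = 1L))
  }
  head_p <- function(cin) {
    d <- 49L * cin
    list(fc1 = list(W = mk(c(d, cfg$fc), d), b = mk(cfg$fc, 1, zero = TRUE)),
         fc2 = list(W = mk(c(cfg$fc, cfg$fc), cfg$fc), b = mk(cfg$fc, 1, zero = TRUE)),
         cls = list(W = mk(c(cfg$fc, 3L), cfg$fc), b = mk(3L, 1, zero = TRUE)),
         reg = list(W = mk(c(cfg$fc, 8L), cfg$fc), b = mk(8L, 1, zero = TRUE)))
  }

  params <- with_seed(seed, {
    p <- list()
    p$backbone_rgb <- backbone_p()
    p$backbone_pha <- if (share_weights) p$backbone_rgb else backbone_p()
    p$hyper_rgb <- hyper_p()
    p$hyper_pha <- if (share_weights) p$hyper_rgb else hyper_p()
    ch5 <- cfg$channels[5]
    p$rpn <- list(rgb = rpn_p(ch5), pha = rpn_p(ch5), corr = rpn_p(cfg$hyper_c))
    p$head <- list(rgb = head_p(ch5), pha = head_p(ch5), corr = head_p(cfg$hyper_c))
    p
  })
  structure(list(params = params, config = cfg, seed = seed),
            class = "weednet")
}

#' @export
print.weednet <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), function(p) length(p$value), numeric(1)))
  cat(sprintf("<weednet> %s backbone, %s weights, %d anchors/location, %s parameters\n",
              x$config$variant,
              if (x$config$share_weights) "shared RGB/PHA" else "separate",
              length(x$config$anchor_scales) * length(x$config$anchor_ratios),
              format(np, big.mark = ",")))
  invisible(x)
}

# ---- forward pieces --------------------------------------------------------

# five conv blocks with stride-2 pooling after blocks 1-4; per-channel RMS
# response normalisation after each block keeps activations well-scaled so
# the network trains from scratch without a pretrained backbone
backbone_forward <- function(tape, xN, P) {
  taps <- list()
  cur <- xN
  for (b in 1:5) {
    for (l in seq_along(P[[b]])) {
      cur <- ag_relu(tape, ag_conv2d(tape, cur,
                                     ag_param(tape, P[[b]][[l]]$W),
                                     ag_param(tape, P[[b]][[l]]$b)))
    }
    cur <- ag_rmsnorm(tape, cur)
    taps[[b]] <- cur
    if (b < 5) cur <- ag_maxpool(tape, cur, 2L)
  }
  taps
}

#' Multiscale hyper feature from backbone taps
#'
#' Combines the block-1 (stride 1), block-3 (stride 4) and block-5
#' (stride 16) feature maps at block-3 resolution: block 1 max-pooled 4x,
#' block 5 upsampled by a learned 4x transposed convolution, then per-channel
#' RMS normalisation, channel concatenation and a learned 1x1 projection.
#' Internal; exposed for tests through [weednet_forward()].
#' @noRd
hyper_forward <- function(tape, taps, P) {
  b1 <- ag_maxpool(tape, taps[[1]], 4L)
  b3 <- taps[[3]]
  ch5 <- dim(taps[[5]]$value)[3]
  b5 <- ag_deconv(tape, taps[[5]], ag_param(tape, P$deconv$W),
                  ag_param(tape, P$deconv$b), k = 4L, Cout = ch5)
  if (!identical(dim(b1$value)[1:2], dim(b3$value)[1:2]) ||
      !identical(dim(b5$value)[1:2], dim(b3$value)[1:2])) {
    stop("hyper_forward(): resampled block shapes disagree: ",
         paste(dim(b1$value)[1:2], collapse = "x"), " / ",
         paste(dim(b3$value)[1:2], collapse = "x"), " / ",
         paste(dim(b5$value)[1:2], collapse = "x"))
  }
  cat <- ag_concat3(tape, list(ag_rmsnorm(tape, b1), ag_rmsnorm(tape, b3),
                               ag_rmsnorm(tape, b5)))
  ag_relu(tape, ag_conv2d(tape, cat, ag_param(tape, P$proj$W),
                          ag_param(tape, P$proj$b), pad = 0L))
}

rpn_forward <- function(tape, featN, P) {
  mid <- ag_relu(tape, ag_conv2d(tape, featN, ag_param(tape, P$mid$W),
                                 ag_param(tape, P$mid$b)))
  list(obj = ag_conv2d(tape, mid, ag_param(tape, P$obj$W),
                       ag_param(tape, P$obj$b), pad = 0L),
       reg = ag_conv2d(tape, mid, ag_param(tape, P$reg$W),
                       ag_param(tape, P$reg$b), pad = 0L))
}

head_forward <- function(tape, featN, rois, stride, P) {
  pooled <- ag_roipool(tape, featN, rois, stride, bins = 7L)
  f1 <- ag_relu(tape, ag_linear(tape, pooled, ag_param(tape, P$fc1$W),
                                ag_param(tape, P$fc1$b)))
  f2 <- ag_relu(tape, ag_linear(tape, f1, ag_param(tape, P$fc2$W),
                                ag_param(tape, P$fc2$b)))
  list(cls = ag_linear(tape, f2, ag_param(tape, P$cls$W), ag_param(tape, P$cls$b)),
       reg = ag_linear(tape, f2, ag_param(tape, P$reg$W), ag_param(tape, P$reg$b)))
}

#' Anchor boxes over a feature grid
#'
#' One anchor per (scale, ratio) at every feature-map cell, centred on the
#' cell centre in input-pixel coordinates; width `scale/sqrt(ratio)`, height
#' `scale*sqrt(ratio)`. Row order matches the column-major layout of the RPN
#' output arrays.
#'
#' @param h,w feature-map size (cells).
#' @param stride feature stride in input pixels.
#' @param scales,ratios anchor generation parameters.
#' @return box matrix with `h*w*length(scales)*length(ratios)` rows.
#' @export
anchor_grid <- function(h, w, stride, scales = c(8, 16, 32), ratios = c(0.5, 1, 2)) {
  cy <- (rep(0:(h - 1), w) + 0.5) * stride
  cx <- (rep(0:(w - 1), each = h) + 0.5) * stride
  out <- vector("list", length(scales) * length(ratios))
  i <- 0L
  for (r in ratios) for (s in scales) {
    i <- i + 1L
    aw <- s / sqrt(r); ah <- s * sqrt(r)
    out[[i]] <- cbind(x1 = cx - aw / 2, y1 = cy - ah / 2,
                      x2 = cx + aw / 2, y2 = cy + ah / 2)
  }
  do.call(rbind, out)
}

#' Label anchors against ground-truth boxes
#'
#' Two kinds of anchors are positive: those with the highest IoU overlap
#' with some ground-truth box (so every ground-truth box gets at least one
#' positive anchor even when all overlaps are below the threshold), and
#' those with IoU above `pos_iou` with any ground-truth box. Anchors with
#' maximum IoU below `neg_iou` are negative; the remainder are ignored.
#'
#' @param anchors box matrix.
#' @param gt_boxes box matrix (may have zero rows).
#' @param pos_iou,neg_iou thresholds (defaults 0.7 / 0.3).
#' @return list with `labels` (1 positive, 0 negative, NA ignore) and
#'   `matched` (index of the matched ground-truth box for positives).
#' @export
assign_anchor_labels <- function(anchors, gt_boxes, pos_iou = 0.7, neg_iou = 0.3,
                                 band = 1e-9) {
  anchors <- as_box_matrix(anchors)
  gt_boxes <- as_box_matrix(gt_boxes)
  n <- nrow(anchors)
  if (nrow(gt_boxes) == 0L) {
    return(list(labels = rep(0, n), matched = rep(NA_integer_, n)))
  }
  iou <- box_iou(anchors, gt_boxes)
  best_gt <- max.col(iou, ties.method = "first")
  best_iou <- iou[cbind(seq_len(n), best_gt)]
  labels <- rep(NA_real_, n)
  labels[best_iou < neg_iou] <- 0
  labels[best_iou >= pos_iou] <- 1
  # highest-overlap rule: every gt's argmax anchors are positive; anchors
  # within a small band of the maximum count as equally "highest", which
  # gives each object a handful of regression examples instead of one
  for (j in seq_len(nrow(gt_boxes))) {
    mx <- max(iou[, j])
    if (mx > 0) {
      hit <- which(iou[, j] >= mx - band)
      labels[hit] <- 1
      best_gt[hit] <- j
    }
  }
  matched <- ifelse(labels == 1, best_gt, NA_integer_)
  list(labels = labels, matched = matched)
}

#' Region-proposal multi-task loss
#'
#' `L = (1/N_cls) sum_i L_cls(p_i, p*_i) + lambda (1/N_reg) sum_i p*_i
#' SmoothL1(t_i - t*_i)` with log loss for `L_cls`; the regression term runs
#' only over positive anchors and sums over the four delta components. Pure
#' arithmetic on predicted probabilities/deltas — the training path computes
#' the same quantity from logits on the autograd tape.
#'
#' @param p predicted objectness probabilities.
#' @param p_star 0/1 anchor labels.
#' @param t,t_star predicted and target delta matrices (n x 4).
#' @param lambda balance weight (default 10).
#' @param n_cls,n_reg normalisers: sampled mini-batch size and number of
#'   anchor locations.
#' @export
rpn_loss <- function(p, p_star, t, t_star, lambda = 10,
                     n_cls = length(p), n_reg = length(p)) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  cls <- -sum(p_star * log(p) + (1 - p_star) * log(1 - p)) / n_cls
  reg <- 0
  pos <- which(p_star == 1)
  if (length(pos)) {
    reg <- sum(smooth_l1(t[pos, , drop = FALSE] - t_star[pos, , drop = FALSE]))
  }
  cls + lambda * reg / n_reg
}

#' Hadamard fusion of two co-registered feature maps
#'
#' Strict elementwise product; the cross-modal fusion used by the correlated
#' branch.
#'
#' @param f_rgb,f_pha equal-shaped numeric arrays.
#' @export
hadamard_fuse <- function(f_rgb, f_pha) {
  if (!identical(dim(f_rgb), dim(f_pha))) stop("hadamard_fuse(): shape mismatch")
  f_rgb * f_pha
}

# proposals from RPN outputs (plain values, no gradient). The reg map
# stores anchor a's four components interleaved in channels 4(a-1)+1..4;
# reg_indices() is the single source of truth for that layout.
rpn_proposals <- function(obj, reg, anchors, img_w, img_h,
                          pre_nms = 384L, post_nms = 48L, nms_iou = 0.7) {
  score <- stats::plogis(as.vector(obj))
  n <- nrow(anchors)
  h <- dim(reg)[1]; w <- dim(reg)[2]; A <- dim(reg)[3] %/% 4L
  ridx <- reg_indices(h, w, A, seq_len(n))
  deltas <- matrix(reg[ridx], n, 4)
  # numerical guard on untrained outputs: cap box growth at exp(4)
  deltas <- pmin(pmax(deltas, -4), 4)
  boxes <- decode_box_deltas(deltas, anchors)
  boxes <- clip_boxes(boxes, img_w, img_h)
  keepsz <- which((boxes[, 3] - boxes[, 1]) >= 2 & (boxes[, 4] - boxes[, 2]) >= 2)
  if (!length(keepsz)) return(list(boxes = matrix(numeric(0), 0, 4), scores = numeric(0)))
  boxes <- boxes[keepsz, , drop = FALSE]; score <- score[keepsz]
  ord <- utils::head(order(score, decreasing = TRUE), pre_nms)
  boxes <- boxes[ord, , drop = FALSE]; score <- score[ord]
  keep <- utils::head(nms(boxes, score, nms_iou), post_nms)
  list(boxes = boxes[keep, , drop = FALSE], scores = score[keep])
}

# reg output layout: array (h, w, 4*A) where the 4 delta components of
# anchor a occupy channels (a-1)*4 + 1:4; linear indices for anchor rows
reg_indices <- function(h, w, A, anchor_rows) {
  # anchor row i (1-based) = ho + h*wo + h*w*(a-1) + 1
  i0 <- anchor_rows - 1L
  ho <- i0 %% h
  wo <- (i0 %/% h) %% w
  a <- i0 %/% (h * w)
  base <- ho + h * wo
  cbind(base + (h * w) * (a * 4L) + 1L,
        base + (h * w) * (a * 4L + 1L) + 1L,
        base + (h * w) * (a * 4L + 2L) + 1L,
        base + (h * w) * (a * 4L + 3L) + 1L)
}

branch_stride <- function(branch) if (branch == "corr") 4L else 16L

# run all three branches; returns per-branch feature nodes, rpn outputs and
# the tape (training and inference share this path)
weednet_graph <- function(net, rgb, pha) {
  if (!identical(dim(rgb)[1:2], dim(pha)[1:2])) {
    stop("weednet: RGB and PHA rasters are not co-registered (",
         paste(dim(rgb)[1:2], collapse = "x"), " vs ",
         paste(dim(pha)[1:2], collapse = "x"), ")")
  }
  tape <- new_tape()
  xr <- ag_leaf(tape, rgb / 255 - 0.5)
  xp <- ag_leaf(tape, pha / 255 - 0.5)
  P <- net$params
  taps_r <- backbone_forward(tape, xr, P$backbone_rgb)
  taps_p <- backbone_forward(tape, xp, P$backbone_pha)
  hy_r <- hyper_forward(tape, taps_r, P$hyper_rgb)
  hy_p <- hyper_forward(tape, taps_p, P$hyper_pha)
  # elementwise product of two rectified maps is sparse and small; RMS
  # response normalisation restores a trainable scale without altering the
  # fusion itself
  corr <- ag_rmsnorm(tape, ag_hadamard(tape, hy_r, hy_p))
  feats <- list(rgb = taps_r[[5]], pha = taps_p[[5]], corr = corr)
  rpns <- list(rgb = rpn_forward(tape, feats$rgb, P$rpn$rgb),
               pha = rpn_forward(tape, feats$pha, P$rpn$pha),
               corr = rpn_forward(tape, feats$corr, P$rpn$corr))
  list(tape = tape, feats = feats, rpns = rpns)
}

#' Run the three-branch detector on one RGB/PHA pair
#'
#' Forward pass in evaluation mode: each branch generates proposals from its
#' RPN (greedy NMS at IoU 0.7), refines and classifies them with its RoI
#' head, applies a score threshold and per-class NMS, and returns its
#' detections. Deterministic.
#'
#' @param net a [weednet()].
#' @param rgb `H x W x 3` colour raster (0..255).
#' @param pha `H x W x 3` quantized PHA raster (0..255).
#' @param image_id identifier recorded in the output.
#' @param score_threshold minimum class score kept (default 0.05).
#' @param final_nms_iou per-class NMS threshold on head outputs (default 0.3).
#' @return tibble of detections with columns `image_id, class, x1, y1, x2,
#'   y2, score, branch` (branches `rgb`, `pha`, `corr`).
#' @export
weednet_forward <- function(net, rgb, pha, image_id = "image",
                            score_threshold = 0.05, final_nms_iou = 0.3) {
  g <- weednet_graph(net, rgb, pha)
  img_h <- dim(rgb)[1]; img_w <- dim(rgb)[2]
  cfg <- net$config
  out <- list()
  for (branch in c("rgb", "pha", "corr")) {
    feat <- g$feats[[branch]]
    stride <- branch_stride(branch)
    fh <- dim(feat$value)[1]; fw <- dim(feat$value)[2]
    anchors <- anchor_grid(fh, fw, stride, cfg$anchor_scales, cfg$anchor_ratios)
    pr <- rpn_proposals(g$rpns[[branch]]$obj$value, g$rpns[[branch]]$reg$value,
                        anchors, img_w, img_h)
    if (!nrow(pr$boxes)) { out[[branch]] <- empty_detections(image_id, branch); next }
    hd <- head_forward(g$tape, feat, pr$boxes, stride, net$params$head[[branch]])
    probs <- softmax_rows(hd$cls$value)
    dets <- list()
    for (k in 1:2) {
      deltas <- hd$reg$value[, (k - 1) * 4 + 1:4, drop = FALSE]
      boxes <- clip_boxes(decode_box_deltas(deltas, pr$boxes), img_w, img_h)
      sc <- probs[, k]
      ok <- which(sc >= score_threshold &
                    boxes[, 3] - boxes[, 1] >= 1 & boxes[, 4] - boxes[, 2] >= 1)
      if (!length(ok)) next
      keep <- nms(boxes[ok, , drop = FALSE], sc[ok], final_nms_iou)
      sel <- ok[keep]
      dets[[k]] <- tibble::tibble(image_id = image_id, class = cfg$classes[k],
                                  x1 = boxes[sel, 1], y1 = boxes[sel, 2],
                                  x2 = boxes[sel, 3], y2 = boxes[sel, 4],
                                  score = sc[sel], branch = branch)
    }
    out[[branch]] <- if (length(dets)) {
      dplyr::arrange(dplyr::bind_rows(dets), class, dplyr::desc(score))
    } else empty_detections(image_id, branch)
  }
  dplyr::bind_rows(out)
}

empty_detections <- function(image_id = character(0), branch = character(0)) {
  tibble::tibble(image_id = character(0), class = character(0),
                 x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                 y2 = numeric(0), score = numeric(0), branch = character(0))
}

softmax_rows <- function(z) {
  zs <- z - apply(z, 1, max)
  ez <- exp(zs)
  ez / rowSums(ez)
}
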