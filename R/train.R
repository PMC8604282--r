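#' Training hyperparameters
#'
#' Mirrors the training schedule of the detection network: plain stochastic
#' gradient descent with momentum, each mini-batch drawn from a single image.
#'
#' @param initial_learning_rate SGD learning rate (default 0.001).
#' @param momentum momentum coefficient (default 0.9).
#' @param weight_decay L2 weight decay (default 0.0001).
#' @param iterations_per_epoch,epochs schedule bookkeeping; the effective
#'   iteration count passed to [train_weednet()] caps the product.
#' @param lambda balance between the RPN classification and regression terms
#'   (default 10, making the two comparably scaled under their normalisers).
#' @export
#' @param lr_decay_factor,lr_decay_at the learning rate starts at
#'   `initial_learning_rate` and is multiplied by `lr_decay_factor` once the
#'   run passes the fraction `lr_decay_at` of its iterations (set
#'   `lr_decay_factor = 1` for a constant rate).
#' @export
train_config <- function(initial_learning_rate = 0.001, momentum = 0.9,
                         weight_decay = 0.0001, iterations_per_epoch = 1000L,
                         epochs = 300L, lambda = 10,
                         lr_decay_factor = 0.1, lr_decay_at = 0.7) {
  structure(list(initial_learning_rate = initial_learning_rate,
                 momentum = momentum, weight_decay = weight_decay,
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 epochs = as.integer(epochs), lambda = lambda,
                 lr_decay_factor = lr_decay_factor, lr_decay_at = lr_decay_at),
            class = "train_config")
}

# sample an RPN mini-batch: all positives plus `neg_per_pos` negatives per
# positive (at least `min_neg`). Small balanced batches keep the per-anchor
# classification gradient large under the 1/N_cls normaliser, which is what
# makes from-scratch training converge within a few hundred steps on the
# small rasters this package targets; N_cls in the loss is the realised
# sample size.
sample_rpn_batch <- function(labels, scores = NULL, neg_per_pos = 3L,
                             min_neg = 8L, cap = 64L) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) > cap / 2) pos <- sample(pos, cap / 2)
  n_neg <- min(length(neg), max(min_neg, neg_per_pos * length(pos)), cap - length(pos))
  if (length(neg) > n_neg) {
    if (!is.null(scores)) {
      # hard negative mining: half the negatives are the currently
      # highest-scoring ones (the anchors polluting the proposal ranking),
      # the other half random for coverage
      n_hard <- ceiling(n_neg / 2)
      hard <- neg[order(scores[neg], decreasing = TRUE)[seq_len(n_hard)]]
      rest <- setdiff(neg, hard)
      neg <- c(hard, sample(rest, n_neg - n_hard))
    } else {
      neg <- sample(neg, n_neg)
    }
  }
  list(pos = pos, neg = neg)
}

branch_losses <- function(tape, net, g, branch, gt_boxes, gt_classes,
                          img_w, img_h, lambda) {
  cfg <- net$config
  feat <- g$feats[[branch]]
  stride <- branch_stride(branch)
  fh <- dim(feat$value)[1]; fw <- dim(feat$value)[2]
  A <- length(cfg$anchor_scales) * length(cfg$anchor_ratios)
  anchors <- anchor_grid(fh, fw, stride, cfg$anchor_scales, cfg$anchor_ratios)
  asg <- assign_anchor_labels(anchors, gt_boxes)
  smp <- sample_rpn_batch(asg$labels,
                          scores = as.vector(g$rpns[[branch]]$obj$value))
  idx <- c(smp$pos, smp$neg)
  targets <- c(rep(1, length(smp$pos)), rep(0, length(smp$neg)))
  n_cls <- max(length(idx), 1L)
  n_reg <- fh * fw
  obj_loss <- ag_bce_logits(tape, g$rpns[[branch]]$obj, idx, targets, 1 / n_cls)

  losses <- list(obj_loss)
  if (length(smp$pos)) {
    tstar <- encode_box_deltas(as_box_matrix(gt_boxes)[asg$matched[smp$pos], , drop = FALSE],
                               anchors[smp$pos, , drop = FALSE])
    ridx <- reg_indices(fh, fw, A, smp$pos)
    losses <- c(losses, list(
      ag_smooth_l1_sel(tape, g$rpns[[branch]]$reg, as.vector(ridx),
                       as.vector(tstar), lambda / n_reg)))
  }

  # RoI head: current proposals plus the ground-truth boxes (and jittered
  # copies, so the head sees near-miss positives before the RPN warms up)
  pr <- rpn_proposals(g$rpns[[branch]]$obj$value, g$rpns[[branch]]$reg$value,
                      anchors, img_w, img_h)
  gtm <- as_box_matrix(gt_boxes)
  jit <- if (nrow(gtm)) {
    # two jitter scales: near-miss positives and proposal-like offsets, so
    # the head's regressor sees the offset range it must correct at test time
    j <- gtm[rep(seq_len(nrow(gtm)), 4L), , drop = FALSE]
    w <- j[, 3] - j[, 1]; h <- j[, 4] - j[, 2]
    amp <- rep(c(0.1, 0.25), each = 2L * nrow(gtm))
    off <- matrix(stats::runif(length(j), -1, 1), nrow(j)) * amp
    clip_boxes(j + off * cbind(w, h, w, h), img_w, img_h)
  } else gtm
  rois <- rbind(pr$boxes, gtm, jit)
  rois <- rois[(rois[, 3] - rois[, 1]) >= 2 & (rois[, 4] - rois[, 2]) >= 2, , drop = FALSE]
  if (nrow(rois)) {
    if (nrow(gt_boxes)) {
      iou <- box_iou(rois, gt_boxes)
      bg <- max.col(iou, ties.method = "first")
      biou <- iou[cbind(seq_len(nrow(rois)), bg)]
      roi_cls <- ifelse(biou >= 0.5, match(gt_classes, weed_classes)[bg], 3L)
    } else {
      roi_cls <- rep(3L, nrow(rois))
      biou <- rep(0, nrow(rois)); bg <- rep(NA_integer_, nrow(rois))
    }
    # balanced RoI batch: all foreground (capped) + an equal number of
    # background rois, so the softmax head trains at the same pace as the RPN
    fg <- which(roi_cls != 3L); bgr <- which(roi_cls == 3L)
    if (length(fg) > 16L) fg <- sample(fg, 16L)
    nb <- min(length(bgr), max(4L, length(fg)))
    if (length(bgr) > nb) bgr <- sample(bgr, nb)
    sel <- c(fg, bgr)
    rois <- rois[sel, , drop = FALSE]
    roi_cls <- roi_cls[sel]; bg <- bg[sel]; biou <- biou[sel]
    hd <- head_forward(tape, feat, rois, stride, net$params$head[[branch]])
    losses <- c(losses, list(ag_softmax_ce(tape, hd$cls, roi_cls)))
    pos <- which(roi_cls != 3L)
    if (length(pos)) {
      tstar <- encode_box_deltas(as_box_matrix(gt_boxes)[bg[pos], , drop = FALSE],
                                 rois[pos, , drop = FALSE])
      n <- nrow(hd$reg$value)
      cols <- (roi_cls[pos] - 1L) * 4L
      ridx <- cbind(pos + n * cols, pos + n * (cols + 1L),
                    pos + n * (cols + 2L), pos + n * (cols + 3L))
      losses <- c(losses, list(
        ag_smooth_l1_sel(tape, hd$reg, as.vector(ridx), as.vector(tstar),
                         1 / length(pos))))
    }
  }
  losses
}

#' Train the three-branch detector
#'
#' End-to-end stochastic gradient descent: each iteration draws one image,
#' computes the three branches' region-proposal losses (objectness log loss
#' plus smooth-L1 box regression under the stated normalisers) and RoI-head
#' losses (softmax cross-entropy plus class-wise smooth-L1), sums them, and
#' takes one SGD step with momentum and weight decay. The correlated and
#' modality-specific branches are trained simultaneously with the same
#' supervision; with weight sharing enabled the RGB and PHA backbones are
#' the same parameter tensors and receive summed gradients.
#'
#' @param net a [weednet()]; updated in place (parameter environments) and
#'   returned invisibly inside the fit object.
#' @param dataset list of samples, each a list with `rgb` (`H x W x 3`,
#'   0..255), `pha` (`H x W x 3`, 0..255) and `annotations` (tibble
#'   `class, x1, y1, x2, y2`).
#' @param iterations number of SGD steps.
#' @param config a [train_config()].
#' @param seed seed for image sampling and anchor subsampling.
#' @param log_every record the loss every this many iterations (1 = all).
#' @return a `weednet_fit`: list with the trained `net`, the `loss_log`
#'   tibble (iteration, total and per-component losses) and the resolved
#'   config.
#' @export
train_weednet <- function(net, dataset, iterations = 500L,
                          config = train_config(), seed = 1L, log_every = 1L) {
  stopifnot(inherits(net, "weednet"), length(dataset) >= 1L)
  params_flat <- flatten_params(net$params)
  # deduplicate shared parameter environments by id
  ids <- vapply(params_flat, function(p) p$id, character(1))
  params_flat <- params_flat[!duplicated(ids)]
  log <- vector("list", iterations)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      s <- dataset[[sample.int(length(dataset), 1L)]]
      img_h <- dim(s$rgb)[1]; img_w <- dim(s$rgb)[2]
      gt_boxes <- as_box_matrix(s$annotations)
      g <- weednet_graph(net, s$rgb, s$pha)
      losses <- list()
      for (branch in c("rgb", "pha", "corr")) {
        losses <- c(losses, branch_losses(g$tape, net, g, branch, gt_boxes,
                                          s$annotations$class, img_w, img_h,
                                          config$lambda))
      }
      total <- ag_add_scalars(g$tape, losses)
      if (!is.finite(total$value)) {
        stop("train_weednet(): non-finite loss at iteration ", it,
             " (", format(total$value), "); training diverged")
      }
      ag_backward(g$tape, total)
      grads <- collect_param_grads(g$tape)
      lr <- config$initial_learning_rate *
        if (it > config$lr_decay_at * iterations) config$lr_decay_factor else 1
      sgd_update(params_flat, grads, lr, config$momentum, config$weight_decay)
      if (it %% log_every == 0L) {
        log[[it]] <- tibble::tibble(iteration = it, loss = total$value)
      }
    }
  })
  structure(list(net = net, loss_log = dplyr::bind_rows(log), config = config,
                 iterations = as.integer(iterations), n_images = length(dataset)),
            class = "weednet_fit")
}

#' @export
print.weednet_fit <- function(x, ...) {
  cat(sprintf("<weednet_fit> %d iterations on %d images; loss %.3f -> %.3f\n",
              x$iterations, x$n_images,
              x$loss_log$loss[1], utils::tail(x$loss_log$loss, 1)))
  invisible(x)
}

#' Detect weeds in a set of scenes
#'
#' Convenience wrapper: runs [weednet_forward()] over a list of samples
#' (named as in [train_weednet()]) and binds the three branches' detections.
#'
#' @param net a trained [weednet()] (or the `net` of a `weednet_fit`).
#' @param dataset list of samples with `rgb`, `pha` and optional `image_id`.
#' @inheritParams weednet_forward
#' @export
detect_weeds <- function(net, dataset, score_threshold = 0.05,
                         final_nms_iou = 0.3) {
  if (inherits(net, "weednet_fit")) net <- net$net
  dplyr::bind_rows(lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    id <- s$image_id %||% sprintf("image_%03d", i)
    weednet_forward(net, s$rgb, s$pha, image_id = id,
                    score_threshold = score_threshold,
                    final_nms_iou = final_nms_iou)
  }))
}

#' Build a training dataset from generated scenes
#'
#' Generates `n` scenes (seeds `seed + 0:(n-1)` on a fixed config), fills
#' depth holes, recodes to PHA and returns the sample list consumed by
#' [train_weednet()] / [detect_weeds()].
#'
#' @param n number of scenes.
#' @param config a [scene_config()]; its seed field is replaced per scene.
#' @param params a [recode_params()].
#' @param seed base seed.
#' @export
make_scene_dataset <- function(n, config = scene_config(), params = recode_params(),
                               seed = 1L) {
  lapply(seq_len(n), function(i) {
    cfg <- config; cfg$seed <- as.integer(seed + i - 1L)
    p <- generate_scene(cfg)
    filled <- fill_holes(p$depth)
    pha <- suppressWarnings(recode_to_pha(filled, p$camera, params))
    list(image_id = sprintf("scene_%03d", i), rgb = p$rgb,
         pha = pha$quantized, annotations = p$annotations, scene = p)
  })
}
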