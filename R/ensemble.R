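#' Ensemble weights for decision-level fusion
#'
#' The fused detector output is the weighted combination
#' `G(x) = alpha * g_RGB(x) + beta * g_PHA(x) + (1 - alpha - beta) *
#' g_corr(x)` over the three branches, with `alpha >= 0`, `beta >= 0`,
#' `alpha + beta <= 1`.
#'
#' @param alpha,beta weights of the RGB and PHA (depth) branches.
#' @export
ensemble_weights <- function(alpha, beta) {
  if (alpha < 0 || beta < 0 || alpha + beta > 1 + 1e-9) {
    stop("ensemble_weights(): need alpha >= 0, beta >= 0, alpha + beta <= 1")
  }
  structure(list(alpha = alpha, beta = beta, gamma = 1 - alpha - beta),
            class = "ensemble_weights")
}

#' Decision-level weighted fusion of branch detections
#'
#' Same-class detections from the three branches are clustered greedily:
#' working down the pooled score ranking, each unused detection seeds a
#' cluster and absorbs at most one unused detection per other branch with
#' IoU at least `cluster_iou`. A cluster's fused score is
#' `alpha * s_rgb + beta * s_pha + (1 - alpha - beta) * s_corr`, with absent
#' members contributing 0; its box is the mean of member boxes weighted by
#' their ensemble-weighted scores (so a branch with weight 0 does not move
#' the box, and corner weights reproduce single branches exactly). Clusters
#' whose fused score is 0 are dropped.
#'
#' @param detections tibble of detections from all three branches of one
#'   image (columns `class, x1, y1, x2, y2, score, branch`).
#' @param weights an [ensemble_weights()].
#' @param cluster_iou clustering threshold (default 0.5).
#' @param average_boxes if `FALSE`, keep the seed member's box instead of
#'   the weighted mean.
#' @return tibble of fused detections (branch `"ensemble"`), sorted by
#'   descending fused score within class.
#' @export
fuse_detections <- function(detections, weights, cluster_iou = 0.5,
                            average_boxes = TRUE) {
  stopifnot(inherits(weights, "ensemble_weights"))
  wmap <- c(rgb = weights$alpha, pha = weights$beta, corr = weights$gamma)
  bad <- setdiff(unique(detections$branch), names(wmap))
  if (length(bad)) stop("fuse_detections(): unknown branch: ", paste(bad, collapse = ", "))
  out <- list()
  for (img in unique(detections$image_id)) {
    for (cl in unique(detections$class[detections$image_id == img])) {
      d <- detections[detections$image_id == img & detections$class == cl, ]
      d <- d[order(-d$score), ]
      used <- rep(FALSE, nrow(d))
      boxes <- as_box_matrix(d)
      for (i in seq_len(nrow(d))) {
        if (used[i]) next
        used[i] <- TRUE
        members <- i
        for (br in setdiff(names(wmap), d$branch[i])) {
          cand <- which(!used & d$branch == br)
          if (!length(cand)) next
          ious <- box_iou(boxes[i, , drop = FALSE], boxes[cand, , drop = FALSE])[1, ]
          j <- cand[which.max(ious)]
          if (max(ious) >= cluster_iou) { members <- c(members, j); used[j] <- TRUE }
        }
        wsc <- unname(wmap[d$branch[members]]) * d$score[members]
        fused_score <- sum(wsc)
        if (fused_score <= 0) next
        box <- if (average_boxes && sum(wsc) > 0) {
          colSums(boxes[members, , drop = FALSE] * wsc) / sum(wsc)
        } else boxes[i, ]
        out[[length(out) + 1L]] <- tibble::tibble(
          image_id = img, class = cl,
          x1 = unname(box[1]), y1 = unname(box[2]),
          x2 = unname(box[3]), y2 = unname(box[4]),
          score = fused_score, branch = "ensemble")
      }
    }
  }
  if (!length(out)) return(empty_detections())
  dplyr::arrange(dplyr::bind_rows(out), image_id, class, dplyr::desc(score))
}

#' Grid search over the ensemble weight simplex
#'
#' Evaluates the fused detector at every feasible `(alpha, beta)` on a grid
#' with the given step (`alpha, beta in {0, step, ..., 1}`,
#' `alpha + beta <= 1`; 231 points at step 0.05) against a validation set,
#' and returns the maximiser plus the full score surface. Ties are broken
#' toward smaller `alpha`, then smaller `beta`.
#'
#' @param detections branch detections over the validation images.
#' @param annotations named list: per image a tibble `class, x1, y1, x2, y2`.
#' @param image_sizes named list of `c(width, height)` per image.
#' @param step grid step (must divide 1).
#' @param metric `"map"` (default) or `"iog"`.
#' @param cluster_iou passed to [fuse_detections()].
#' @param ... passed to [evaluate_detections()].
#' @return list with `best` ([ensemble_weights()]), `best_score`, and
#'   `surface` (tibble `alpha, beta, score`).
#' @export
grid_search_weights <- function(detections, annotations, image_sizes,
                                step = 0.05, metric = c("map", "iog"),
                                cluster_iou = 0.5, ...) {
  metric <- match.arg(metric)
  if (!length(annotations)) stop("grid_search_weights(): empty validation set")
  ticks <- round(1 / step)
  if (abs(ticks * step - 1) > 1e-9) stop("grid_search_weights(): step must divide 1")
  grid <- expand.grid(ai = 0:ticks, bi = 0:ticks)
  grid <- grid[grid$ai + grid$bi <= ticks, ]
  grid <- grid[order(grid$ai, grid$bi), ]
  scores <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    w <- ensemble_weights(grid$ai[r] * step, grid$bi[r] * step)
    fused <- fuse_detections(detections, w, cluster_iou = cluster_iou)
    # per-point diagnostics (e.g. a class with no validation ground truth)
    # would repeat across the whole grid; keep the search quiet
    ev <- suppressWarnings(evaluate_detections(fused, annotations, image_sizes, ...))
    scores[r] <- if (metric == "map") ev$map else ev$iog
  }
  best_r <- which.max(scores)   # grid sorted by (alpha, beta): first max wins ties
  list(best = ensemble_weights(grid$ai[best_r] * step, grid$bi[best_r] * step),
       best_score = scores[best_r],
       surface = tibble::tibble(alpha = grid$ai * step, beta = grid$bi * step,
                                score = scores))
}
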