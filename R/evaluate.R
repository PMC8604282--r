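#' Match detections against ground truth
#'
#' Greedy matching in descending score order within each image and class:
#' a detection is a true positive if its IoU with a not-yet-matched
#' same-class ground-truth box reaches `iou_threshold`; each ground-truth
#' box can be matched at most once, so duplicate detections of one object
#' count as false positives.
#'
#' @param detections detections tibble (one image, one class, or any mix —
#'   matching is grouped by `image_id` and `class`).
#' @param annotations named list of per-image annotation tibbles.
#' @param iou_threshold match threshold (default 0.5, the Pascal VOC
#'   convention).
#' @return the detections tibble with a logical `tp` column, sorted by
#'   descending score within image/class.
#' @export
match_detections <- function(detections, annotations, iou_threshold = 0.5) {
  if (!nrow(detections)) {
    return(dplyr::mutate(detections, tp = logical(0)))
  }
  out <- list()
  for (img in unique(detections$image_id)) {
    ann <- annotations[[img]]
    if (is.null(ann)) ann <- tibble::tibble(class = character(0), x1 = numeric(0),
                                            y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
    for (cl in unique(detections$class[detections$image_id == img])) {
      d <- detections[detections$image_id == img & detections$class == cl, ]
      d <- d[order(-d$score), ]
      g <- ann[ann$class == cl, ]
      taken <- rep(FALSE, nrow(g))
      tp <- rep(FALSE, nrow(d))
      if (nrow(g)) {
        iou <- box_iou(d, g)
        for (i in seq_len(nrow(d))) {
          free <- which(!taken)
          if (!length(free)) break
          j <- free[which.max(iou[i, free])]
          if (iou[i, j] >= iou_threshold) { tp[i] <- TRUE; taken[j] <- TRUE }
        }
      }
      d$tp <- tp
      out[[length(out) + 1L]] <- d
    }
  }
  dplyr::bind_rows(out)
}

#' Average precision from matched detections
#'
#' Area under the monotone precision-recall curve. With
#' `interpolation = "all"` (default) the precision at each recall level is
#' replaced by the maximum precision at any equal-or-higher recall (the
#' right envelope) and integrated exactly; `"11point"` averages the
#' interpolated precision at recalls `0, 0.1, ..., 1`.
#'
#' @param tp logical vector of per-detection true-positive flags, in
#'   descending score order.
#' @param n_gt number of ground-truth instances of the class.
#' @param interpolation `"all"` or `"11point"`.
#' @return AP as a percentage in `[0, 100]`; `NA` when `n_gt` is 0.
#' @export
average_precision <- function(tp, n_gt, interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (n_gt == 0L) {
    warning("average_precision(): no ground-truth instances; AP undefined")
    return(NA_real_)
  }
  if (!length(tp)) return(0)
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_gt
  env <- rev(cummax(rev(prec)))
  if (interpolation == "11point") {
    pts <- vapply(seq(0, 1, 0.1), function(r) {
      ok <- rec >= r - 1e-12
      if (any(ok)) max(env[ok]) else 0
    }, numeric(1))
    return(mean(pts) * 100)
  }
  dr <- diff(c(0, rec))
  sum(dr * env) * 100
}

#' Precision-recall curve points
#' @noRd
pr_curve <- function(tp, scores, n_gt) {
  ord <- order(-scores)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  tibble::tibble(score = scores[ord],
                 precision = cum_tp / seq_along(tp),
                 recall = if (n_gt > 0) cum_tp / n_gt else rep(0, length(tp)))
}

#' Intersection over ground truth
#'
#' Pixel-area coverage of the annotated weed regions by the detections:
#' per image, the union of above-threshold detection boxes (class-agnostic
#' over the two weed classes) is rasterised against the union of
#' ground-truth boxes; the metric is the summed intersection area over the
#' summed ground-truth area across the dataset, as a percentage. Robust to
#' the granularity with which clustered weeds were boxed during labelling.
#'
#' @param detections detections tibble.
#' @param annotations named list of per-image annotation tibbles.
#' @param image_sizes named list of `c(width, height)` per image.
#' @param score_threshold detections below this score are ignored
#'   (default 0.5).
#' @param per_class if `TRUE`, additionally restrict to same-class coverage
#'   and return a per-class vector.
#' @return IoG percentage in `[0, 100]`.
#' @export
iog <- function(detections, annotations, image_sizes, score_threshold = 0.5,
                per_class = FALSE) {
  classes <- if (per_class) weed_classes else list(weed_classes)
  res <- vapply(classes, function(cls) {
    inter_a <- 0; gt_a <- 0
    for (img in names(annotations)) {
      ann <- annotations[[img]]
      ann <- ann[ann$class %in% cls, ]
      sz <- image_sizes[[img]]
      gmask <- boxes_mask(ann, sz[1], sz[2])
      d <- detections[detections$image_id == img &
                        detections$score >= score_threshold &
                        detections$class %in% cls, ]
      dmask <- boxes_mask(d, sz[1], sz[2])
      inter_a <- inter_a + sum(gmask & dmask)
      gt_a <- gt_a + sum(gmask)
    }
    if (gt_a == 0) stop("iog(): empty ground-truth area")
    100 * inter_a / gt_a
  }, numeric(1))
  if (per_class) stats::setNames(res, unlist(classes)) else res[[1]]
}

# logical raster of the union of integer-clipped boxes
boxes_mask <- function(boxes, width, height) {
  m <- matrix(FALSE, height, width)
  b <- as_box_matrix(boxes)
  if (nrow(b)) {
    b <- clip_boxes(b, width, height)
    for (i in seq_len(nrow(b))) {
      # half-open boxes: pixel x is covered iff x1 <= x < x2
      xs <- floor(b[i, 1]):(ceiling(b[i, 3]) - 1)
      ys <- floor(b[i, 2]):(ceiling(b[i, 4]) - 1)
      xs <- xs[xs >= 0 & xs < width]; ys <- ys[ys >= 0 & ys < height]
      if (length(xs) && length(ys)) m[ys + 1, xs + 1] <- TRUE
    }
  }
  m
}

#' Evaluate detections: per-class AP, mAP and IoG
#'
#' @param detections detections tibble over a set of images.
#' @param annotations named list (by image id) of annotation tibbles.
#' @param image_sizes named list of `c(width, height)`; a single unnamed
#'   `c(width, height)` is recycled for all images.
#' @param iou_threshold AP match threshold (default 0.5).
#' @param score_threshold IoG detection cutoff (default 0.5).
#' @param interpolation AP interpolation scheme, see [average_precision()].
#' @return a `weed_eval`: list with `per_class` (tibble `class, ap, n_gt,
#'   n_det`), `map`, `iog`, `pr_curves`, and the thresholds used.
#' @export
evaluate_detections <- function(detections, annotations, image_sizes,
                                iou_threshold = 0.5, score_threshold = 0.5,
                                interpolation = "all") {
  if (!is.list(image_sizes) || is.numeric(image_sizes)) {
    image_sizes <- stats::setNames(rep(list(image_sizes), length(annotations)),
                                   names(annotations))
  }
  missing_sz <- setdiff(names(annotations), names(image_sizes))
  if (length(missing_sz)) stop("evaluate_detections(): no image size for ",
                               paste(missing_sz, collapse = ", "))
  stray <- setdiff(unique(detections$image_id), names(annotations))
  if (length(stray)) stop("evaluate_detections(): detections reference unknown image(s): ",
                          paste(stray, collapse = ", "))
  matched <- match_detections(detections, annotations, iou_threshold)
  per_class <- list(); curves <- list()
  aps <- c()
  for (cl in weed_classes) {
    n_gt <- sum(vapply(annotations, function(a) sum(a$class == cl), numeric(1)))
    d <- matched[matched$class == cl, ]
    d <- d[order(-d$score), ]
    ap <- if (n_gt > 0) average_precision(d$tp, n_gt, interpolation) else {
      warning("evaluate_detections(): no '", cl, "' ground truth; class excluded from mAP")
      NA_real_
    }
    aps <- c(aps, ap)
    per_class[[cl]] <- tibble::tibble(class = cl, ap = ap, n_gt = n_gt, n_det = nrow(d))
    curves[[cl]] <- dplyr::mutate(pr_curve(d$tp, d$score, n_gt), class = cl)
  }
  structure(list(per_class = dplyr::bind_rows(per_class),
                 map = mean(aps, na.rm = TRUE),
                 iog = iog(detections, annotations, image_sizes, score_threshold),
                 pr_curves = dplyr::bind_rows(curves),
                 iou_threshold = iou_threshold,
                 score_threshold = score_threshold,
                 interpolation = interpolation),
            class = "weed_eval")
}

#' @export
print.weed_eval <- function(x, ...) {
  cat("<weed_eval>\n")
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("  AP[%s] = %.1f%% (n_gt = %d)\n", x$per_class$class[i],
                x$per_class$ap[i], x$per_class$n_gt[i]))
  }
  cat(sprintf("  mAP = %.1f%%   IoG = %.1f%% (score >= %.2f)\n",
              x$map, x$iog, x$score_threshold))
  invisible(x)
}

#' Per-image detection recall at a fixed IoU
#'
#' Fraction of ground-truth boxes matched by any detection at the given
#' IoU threshold (class-aware), over the whole set.
#'
#' @inheritParams evaluate_detections
#' @export
detection_recall <- function(detections, annotations, iou_threshold = 0.5) {
  matched <- match_detections(detections, annotations, iou_threshold)
  n_gt <- sum(vapply(annotations, nrow, numeric(1)))
  if (n_gt == 0L) return(NA_real_)
  sum(matched$tp) / n_gt
}
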