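#' Plot an RGB-D scene pair
#'
#' Colour image, depth rendering and annotation boxes side by side.
#'
#' @param pair a `scene_pair`.
#' @return a ggplot object.
#' @export
plot_scene <- function(pair) {
  s <- dim(pair$depth$values)
  rgb_df <- raster_df(pair$rgb[, , 1], "RGB")
  rgb_df$fill <- grDevices::rgb(as.vector(pair$rgb[, , 1]),
                                as.vector(pair$rgb[, , 2]),
                                as.vector(pair$rgb[, , 3]), maxColorValue = 255)
  dep <- depth_to_8bit(pair$depth)
  dep_df <- raster_df(dep, "depth")
  dep_df$fill <- grDevices::gray(as.vector(dep) / 255)
  df <- rbind(rgb_df, dep_df)
  ann <- pair$annotations
  ggplot2::ggplot(df) +
    ggplot2::geom_raster(ggplot2::aes(x = .data$x, y = .data$y, fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_rect(data = ann,
                       ggplot2::aes(xmin = .data$x1, xmax = .data$x2,
                                    ymin = .data$y1, ymax = .data$y2,
                                    colour = .data$class),
                       fill = NA, linewidth = 0.4) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = "weed class") +
    ggplot2::theme_minimal()
}

raster_df <- function(m, panel) {
  data.frame(x = rep(seq_len(ncol(m)) - 1, each = nrow(m)),
             y = rep(seq_len(nrow(m)) - 1, ncol(m)),
             fill = NA_character_, panel = panel)
}

#' Plot the three channels of a PHA image
#'
#' @param pha a `pha_image` from [recode_to_pha()].
#' @return a ggplot object faceted by channel.
#' @export
plot_pha <- function(pha) {
  q <- pha$quantized
  chans <- c("phase", "height", "angle")
  df <- do.call(rbind, lapply(1:3, function(c) {
    d <- raster_df(q[, , c], chans[c])
    d$value <- as.vector(q[, , c])
    d
  }))
  df$panel <- factor(df$panel, levels = chans)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "8-bit value") +
    ggplot2::theme_minimal()
}

#' Overlay detections on a scene
#'
#' @param pair a `scene_pair`.
#' @param detections detections tibble for this image (any branches).
#' @param score_threshold hide detections below this score.
#' @export
plot_detections <- function(pair, detections, score_threshold = 0.5) {
  p <- plot_scene(pair)
  d <- detections[detections$score >= score_threshold, ]
  if (nrow(d)) {
    p <- p + ggplot2::geom_rect(
      data = d, ggplot2::aes(xmin = .data$x1, xmax = .data$x2,
                             ymin = .data$y1, ymax = .data$y2,
                             linetype = .data$branch),
      colour = "red", fill = NA, linewidth = 0.4)
  }
  p
}

#' Precision-recall curves of an evaluation report
#'
#' @param object a `weed_eval`.
#' @param ... unused.
#' @method autoplot weed_eval
#' @export
autoplot.weed_eval <- function(object, ...) {
  ggplot2::ggplot(object$pr_curves,
                  ggplot2::aes(x = .data$recall, y = .data$precision,
                               colour = .data$class)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("mAP %.1f%%, IoG %.1f%%", object$map, object$iog),
                  x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' Training loss curve
#'
#' @param object a `weednet_fit`.
#' @param ... unused.
#' @method autoplot weednet_fit
#' @export
autoplot.weednet_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_log, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x) +
    ggplot2::labs(x = "SGD iteration", y = "total loss") +
    ggplot2::theme_minimal()
}

#' Ensemble weight-search surface
#'
#' Heat map of the validation score over the feasible `(alpha, beta)` grid.
#'
#' @param surface the `surface` tibble from [grid_search_weights()].
#' @export
plot_weight_surface <- function(surface) {
  ggplot2::ggplot(surface, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                        fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(alpha~"(RGB weight)"),
                  y = expression(beta~"(PHA weight)"), fill = "score (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
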