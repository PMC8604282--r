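#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted detector: the training loss log
#'
#' @param x a `weednet_fit`.
#' @param ... unused.
#' @return tibble with `iteration` and `loss`.
#' @method tidy weednet_fit
#' @export
tidy.weednet_fit <- function(x, ...) x$loss_log

#' One-row summary of a training run
#'
#' @param x a `weednet_fit`.
#' @param ... unused.
#' @method glance weednet_fit
#' @export
glance.weednet_fit <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$net$params), function(p) length(p$value), numeric(1)))
  tibble::tibble(iterations = x$iterations, n_images = x$n_images,
                 final_loss = utils::tail(x$loss_log$loss, 1),
                 n_parameters = np,
                 backbone = x$net$config$variant,
                 shared_weights = x$net$config$share_weights)
}

#' Tidy an evaluation report: per-class average precision
#'
#' @param x a `weed_eval`.
#' @param ... unused.
#' @method tidy weed_eval
#' @export
tidy.weed_eval <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x a `weed_eval`.
#' @param ... unused.
#' @method glance weed_eval
#' @export
glance.weed_eval <- function(x, ...) {
  tibble::tibble(map = x$map, iog = x$iog,
                 iou_threshold = x$iou_threshold,
                 score_threshold = x$score_threshold)
}
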