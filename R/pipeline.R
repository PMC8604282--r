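#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters: scene generation, PHA recoding,
#' training, ensembling and evaluation. The resolved configuration is
#' written as YAML next to the outputs of every run.
#'
#' @param out_dir output directory.
#' @param n_scenes number of synthetic scenes.
#' @param scene a [scene_config()].
#' @param recode a [recode_params()].
#' @param train a [train_config()].
#' @param iterations SGD iterations for the training stage.
#' @param backbone backbone variant for [weednet()].
#' @param anchor_ratios anchor aspect ratios.
#' @param train_fraction fraction of scenes used for training; the rest form
#'   the validation split used by the weight grid search (train/test 90/10
#'   by default, the dataset's split ratio).
#' @param alpha,beta ensemble weights; `NULL` runs the grid search on the
#'   validation split.
#' @param grid_step grid-search step.
#' @param iou_threshold,score_threshold evaluation thresholds.
#' @param seed master seed; all stage seeds derive from it.
#' @export
pipeline_config <- function(out_dir, n_scenes = 16L,
                            scene = scene_config(image_size = 64L, n_grass = 2L,
                                                 n_broadleaf = 1L),
                            recode = recode_params(),
                            train = train_config(),
                            iterations = 300L, backbone = "tiny",
                            anchor_ratios = c(0.5, 1, 2),
                            train_fraction = 0.9,
                            alpha = NULL, beta = NULL, grid_step = 0.05,
                            iou_threshold = 0.5, score_threshold = 0.5,
                            seed = 1L) {
  if (missing(out_dir) || !nzchar(out_dir)) stop("pipeline_config(): out_dir is required")
  stopifnot(n_scenes >= 2L, train_fraction > 0, train_fraction < 1)
  structure(list(out_dir = out_dir, n_scenes = as.integer(n_scenes),
                 scene = scene, recode = recode, train = train,
                 iterations = as.integer(iterations), backbone = backbone,
                 anchor_ratios = anchor_ratios,
                 train_fraction = train_fraction, alpha = alpha, beta = beta,
                 grid_step = grid_step, iou_threshold = iou_threshold,
                 score_threshold = score_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full detection pipeline
#'
#' Executes generate -> recode -> train -> detect -> ensemble -> evaluate on
#' synthetic scenes, writing each stage's artifacts under `config$out_dir`
#' (`scenes/` PNG + VOC XML, `detections.jsonl`, `ensemble.jsonl`,
#' `evaluation.json`, `config.yaml`). With `resume = TRUE`, stages whose
#' outputs already exist are skipped and their artifacts reloaded, so a run
#' can be restarted after any stage.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse existing stage outputs where present.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the fitted net, detections, fused
#'   detections, chosen weights and the [evaluate_detections()] report.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf("[weedspot %s] ", format(Sys.time(), "%H:%M:%S")), ...)
  cfg_for_yaml <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::write_yaml(cfg_for_yaml, file.path(out, "config.yaml"))

  # stage: generate + recode
  say("stage generate+recode: ", config$n_scenes, " scenes")
  ds <- make_scene_dataset(config$n_scenes, config$scene, config$recode,
                           seed = config$seed)
  scene_dir <- file.path(out, "scenes")
  if (!resume || !dir.exists(scene_dir)) {
    for (i in seq_along(ds)) {
      write_scene_pair(ds[[i]]$scene, scene_dir, ds[[i]]$image_id)
    }
  }
  n_train <- max(1L, floor(config$train_fraction * config$n_scenes))
  train_ds <- ds[seq_len(n_train)]
  val_ds <- ds[setdiff(seq_along(ds), seq_len(n_train))]
  if (!length(val_ds)) val_ds <- train_ds

  anns <- function(d) stats::setNames(lapply(d, function(s) s$annotations),
                                      vapply(d, function(s) s$image_id, character(1)))
  sizes <- function(d) stats::setNames(
    lapply(d, function(s) c(ncol(s$rgb), nrow(s$rgb))),
    vapply(d, function(s) s$image_id, character(1)))

  # stage: train
  say("stage train: ", config$iterations, " iterations (", config$backbone, ")")
  net <- weednet(config$backbone, anchor_ratios = config$anchor_ratios,
                 seed = config$seed)
  fit <- train_weednet(net, train_ds, iterations = config$iterations,
                       config = config$train, seed = config$seed)
  utils::write.csv(fit$loss_log, file.path(out, "loss_log.csv"), row.names = FALSE)

  # stage: detect (three branches, all scenes)
  det_path <- file.path(out, "detections.jsonl")
  if (resume && file.exists(det_path)) {
    say("stage detect: resuming from ", det_path)
    dets <- read_detections_jsonl(det_path)
  } else {
    say("stage detect")
    dets <- detect_weeds(fit, ds)
    write_detections_jsonl(dets, det_path)
  }

  # stage: ensemble (weights fixed or grid-searched on the validation split)
  if (is.null(config$alpha) || is.null(config$beta)) {
    say("stage ensemble: grid search, step ", config$grid_step)
    val_ids <- vapply(val_ds, function(s) s$image_id, character(1))
    gs <- grid_search_weights(dets[dets$image_id %in% val_ids, ],
                              anns(val_ds), sizes(val_ds),
                              step = config$grid_step,
                              iou_threshold = config$iou_threshold,
                              score_threshold = config$score_threshold)
    w <- gs$best
    utils::write.csv(gs$surface, file.path(out, "weight_surface.csv"),
                     row.names = FALSE)
  } else {
    w <- ensemble_weights(config$alpha, config$beta)
  }
  say(sprintf("ensemble weights: alpha=%.2f beta=%.2f", w$alpha, w$beta))
  fused <- fuse_detections(dets, w)
  write_detections_jsonl(fused, file.path(out, "ensemble.jsonl"))

  # stage: evaluate (on the held-out split)
  say("stage evaluate")
  ev <- evaluate_detections(fused[fused$image_id %in% names(anns(val_ds)), ],
                            anns(val_ds), sizes(val_ds),
                            iou_threshold = config$iou_threshold,
                            score_threshold = config$score_threshold)
  jsonlite::write_json(
    list(per_class = ev$per_class, map = ev$map, iog = ev$iog,
         weights = list(alpha = w$alpha, beta = w$beta)),
    file.path(out, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  say(sprintf("done: mAP %.1f%%, IoG %.1f%%", ev$map, ev$iog))
  invisible(list(fit = fit, detections = dets, fused = fused, weights = w,
                 evaluation = ev, dataset = ds))
}
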