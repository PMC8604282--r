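#' Configuration of the synthetic wheat-field scene generator
#'
#' Describes a top-down RGB-D view of a wheat canopy with grass and
#' broad-leaf weeds, emulating field acquisition with a stereo depth rig
#' mounted about 70 cm above the crop. Heights are in millimetres above
#' ground. Defaults follow winter wheat around tillering/jointing: canopy
#' 120-280 mm; grass weeds (wild oat habit) overtop the canopy at
#' 380-520 mm and share the wheat's green hue family, so they are ambiguous
#' in colour but distinct in depth; broad-leaf weeds are low compact
#' rosettes (60-150 mm) distinct in both modalities.
#'
#' @param image_size side length in pixels of the square scene.
#' @param camera_height camera height above ground (mm).
#' @param wheat_height_range,grass_weed_height_range,broadleaf_height_range
#'   `c(min, max)` heights (mm).
#' @param n_grass,n_broadleaf weed instance counts.
#' @param depth_noise_sd Gaussian depth noise (mm).
#' @param hole_fraction expected fraction of depth pixels dropped as invalid
#'   (holes), placed preferentially at depth discontinuities (shielding).
#' @param max_tilt_deg maximum camera tilt off plumb (degrees); the true
#'   gravity direction is recorded per scene.
#' @param seed integer seed; scenes are bit-reproducible given the config.
#' @return a `scene_config`.
#' @export
scene_config <- function(image_size = 500L, camera_height = 700,
                         wheat_height_range = c(120, 280),
                         grass_weed_height_range = c(380, 520),
                         broadleaf_height_range = c(60, 150),
                         n_grass = 3L, n_broadleaf = 2L,
                         depth_noise_sd = 2, hole_fraction = 0.05,
                         max_tilt_deg = 5, seed = 1L) {
  stopifnot(image_size > 0, hole_fraction >= 0, hole_fraction <= 1,
            depth_noise_sd >= 0, n_grass >= 0, n_broadleaf >= 0)
  if (max(wheat_height_range, grass_weed_height_range, broadleaf_height_range)
      >= camera_height) {
    stop("scene_config(): all plant heights must be below camera_height")
  }
  structure(list(image_size = as.integer(image_size),
                 camera_height = camera_height,
                 wheat_height_range = wheat_height_range,
                 grass_weed_height_range = grass_weed_height_range,
                 broadleaf_height_range = broadleaf_height_range,
                 n_grass = as.integer(n_grass), n_broadleaf = as.integer(n_broadleaf),
                 depth_noise_sd = depth_noise_sd, hole_fraction = hole_fraction,
                 max_tilt_deg = max_tilt_deg, seed = as.integer(seed)),
            class = "scene_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# smooth random field in [0, 1] from a small cosine basis
smooth_field <- function(h, w, n_waves = 6, freq = c(2, 6)) {
  u <- matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
  v <- matrix(rep(seq(0, 1, length.out = h), w), h, w)
  f <- matrix(0, h, w)
  for (k in seq_len(n_waves)) {
    fr <- stats::runif(1, freq[1], freq[2]) * 2 * pi
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + cos(fr * (u * cos(th) + v * sin(th)) + ph)
  }
  (f - min(f)) / max(1e-12, diff(range(f)))
}

# elongated stroke mask (grass weed): rotated thin rectangle with ragged ends
stroke_mask <- function(size, cx, cy, len, wid, theta) {
  x <- matrix(rep(0:(size - 1), each = size), size, size) - cx
  y <- matrix(rep(0:(size - 1), size), size, size) - cy
  a <- x * cos(theta) + y * sin(theta)
  b <- -x * sin(theta) + y * cos(theta)
  abs(a) <= len / 2 * (1 - 0.3 * (abs(b) / (wid / 2))^2) & abs(b) <= wid / 2
}

# lobed compact blob mask (broad-leaf rosette)
blob_mask <- function(size, cx, cy, r0, lobes, phase) {
  x <- matrix(rep(0:(size - 1), each = size), size, size) - cx
  y <- matrix(rep(0:(size - 1), size), size, size) - cy
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  r <= r0 * (1 + 0.25 * cos(lobes * th + phase))
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x1 = min(idx[, 2]) - 1, y1 = min(idx[, 1]) - 1,
    x2 = max(idx[, 2]), y2 = max(idx[, 1]))
}

#' Generate one synthetic RGB-D wheat-field scene
#'
#' Renders ground + wheat canopy + weeds under a pinhole camera looking
#' straight down with a small random tilt (recorded as `true_gravity` in the
#' camera frame), producing a paired 8-bit colour raster and a 16-bit-range
#' depth raster (mm) with Gaussian noise and shielding-style holes, plus
#' box annotations for every weed. Deterministic for a fixed config seed.
#'
#' @param config a [scene_config()].
#' @return a `scene_pair`: list with `rgb` (`H x W x 3` integer 0..255),
#'   `depth` ([depth_raster()], noisy, holes as 0), `depth_clean` (noise-free
#'   matrix, mm), `annotations` (tibble `class, x1, y1, x2, y2`),
#'   `true_gravity` (unit 3-vector, camera frame), `camera`
#'   ([camera_rig()]), and `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    s <- config$image_size
    rig <- camera_rig(fx_depth = 1.2 * s, fy_depth = 1.2 * s,
                      cx_depth = (s - 1) / 2, cy_depth = (s - 1) / 2)
    # camera tilt: gravity in camera frame, close to the optical axis
    tilt <- stats::runif(1, 0.2, 1) * config$max_tilt_deg * pi / 180
    psi <- stats::runif(1, 0, 2 * pi)
    g <- c(sin(tilt) * cos(psi), sin(tilt) * sin(psi), cos(tilt))

    # canopy height field (mm above ground), fine texture on smooth waves
    # drilled wheat: canopy rows with bare soil strips between them
    hr <- config$wheat_height_range
    u0 <- matrix(rep(seq(0, 1, length.out = s), each = s), s, s)
    v0 <- matrix(rep(seq(0, 1, length.out = s), s), s, s)
    row_theta <- stats::runif(1, 0, pi)
    row_freq <- stats::runif(1, 2, 4) * 2 * pi               # 15-25 cm drill spacing
    row_phase <- stats::runif(1, 0, 2 * pi)
    rowness <- sin(row_freq * (u0 * cos(row_theta) + v0 * sin(row_theta)) + row_phase)
    wheatness <- pmin(1, pmax(0, (rowness + 0.6) / 0.7))     # ~70% cover, leaning row edges
    # the scene spans well under a metre on the ground, so the canopy surface
    # is a per-scene base height with gentle undulation and leaf-scale relief
    base_h <- stats::runif(1, hr[1], hr[2])
    canopy <- base_h + 60 * (smooth_field(s, s, n_waves = 6, freq = c(1, 3)) - 0.5) +
      16 * (smooth_field(s, s, n_waves = 8, freq = c(6, 14)) - 0.5)
    canopy <- pmin(pmax(canopy, hr[1]), hr[2])
    soil <- 8 * smooth_field(s, s, n_waves = 6, freq = c(4, 10))
    canopy <- wheatness * canopy + (1 - wheatness) * soil

    # place weeds by rejection, limiting pairwise box overlap
    ann <- list(); masks <- list(); heights <- list()
    place <- function(kind) {
      for (try in 1:200) {
        if (kind == "grass") {
          len <- stats::runif(1, 0.18, 0.32) * s
          wid <- max(3, stats::runif(1, 0.025, 0.05) * s)
          cx <- stats::runif(1, len / 2, s - len / 2)
          cy <- stats::runif(1, len / 2, s - len / 2)
          m <- stroke_mask(s, cx, cy, len, wid, stats::runif(1, 0, pi))
          hrange <- config$grass_weed_height_range
        } else {
          r0 <- stats::runif(1, 0.05, 0.09) * s
          cx <- stats::runif(1, 1.3 * r0, s - 1.3 * r0)
          cy <- stats::runif(1, 1.3 * r0, s - 1.3 * r0)
          m <- blob_mask(s, cx, cy, r0, sample(4:6, 1), stats::runif(1, 0, 2 * pi))
          hrange <- config$broadleaf_height_range
        }
        if (!any(m)) next
        bb <- mask_bbox(m)
        ious <- if (length(ann)) {
          box_iou(matrix(bb, 1, 4), do.call(rbind, lapply(ann, function(a) a$box)))
        } else 0
        if (max(ious) <= 0.25) {
          return(list(box = bb, mask = m, h = stats::runif(1, hrange[1], hrange[2]),
                      class = if (kind == "grass") "grass" else "broadleaf"))
        }
      }
      stop("generate_scene(): cannot place weeds without exceeding the maximum overlap; ",
           "reduce weed counts or sizes")
    }
    for (i in seq_len(config$n_grass)) ann[[length(ann) + 1L]] <- place("grass")
    for (i in seq_len(config$n_broadleaf)) ann[[length(ann) + 1L]] <- place("broadleaf")

    height <- canopy
    for (a in ann) {
      hv <- a$h + stats::rnorm(sum(a$mask), 0, 5)
      height[a$mask] <- hv
    }
    height <- pmax(height, 0)

    # exact pinhole depth of the surface point along each pixel ray:
    # d = (camera_height - h) / (g . ray), ray = K^-1 (u, v, 1)'
    K <- rig$K_depth
    u <- matrix(rep(0:(s - 1), each = s), s, s)
    v <- matrix(rep(0:(s - 1), s), s, s)
    rx <- (u - K$cx) / K$fx
    ry <- (v - K$cy) / K$fy
    denom <- g[1] * rx + g[2] * ry + g[3]
    depth_clean <- (config$camera_height - height) / denom

    noisy <- depth_clean + matrix(stats::rnorm(s * s, 0, config$depth_noise_sd), s, s)

    # shielding holes: Bernoulli per pixel, probability inflated at depth
    # discontinuities, mean fixed at hole_fraction
    if (config$hole_fraction > 0) {
      gx <- cbind(abs(depth_clean[, -1] - depth_clean[, -s]), 0)
      gy <- rbind(abs(depth_clean[-1, ] - depth_clean[-s, ]), 0)
      edge <- (pmax(gx, gy) > 30) * 1
      wgt <- 1 + 3 * edge
      p <- pmin(1, config$hole_fraction * wgt / mean(wgt))
      holes <- matrix(stats::runif(s * s) < p, s, s)
      noisy[holes] <- 0
    }
    noisy <- pmax(noisy, 0)

    # colour: wheat and grass weeds share one green hue family (ambiguous);
    # soil strips are brown; broad-leaf weeds a distinct darker blue-green
    shade <- (height - min(height)) / max(1e-9, diff(range(height)))
    tex <- smooth_field(s, s, n_waves = 8, freq = c(8, 20))
    rgb <- array(0, c(s, s, 3))
    rgb[, , 1] <- 62 + 55 * shade + 25 * tex
    rgb[, , 2] <- 105 + 70 * shade + 30 * tex
    rgb[, , 3] <- 38 + 28 * shade + 15 * tex
    soil_w <- (1 - wheatness)
    rgb[, , 1] <- rgb[, , 1] * (1 - soil_w) + soil_w * (118 + 20 * tex)
    rgb[, , 2] <- rgb[, , 2] * (1 - soil_w) + soil_w * (92 + 15 * tex)
    rgb[, , 3] <- rgb[, , 3] * (1 - soil_w) + soil_w * (58 + 10 * tex)
    for (a in ann) {
      if (a$class == "broadleaf") {
        n <- sum(a$mask)
        ch1 <- rgb[, , 1]; ch2 <- rgb[, , 2]; ch3 <- rgb[, , 3]
        ch1[a$mask] <- 30 + stats::rnorm(n, 0, 6)
        ch2[a$mask] <- 95 + stats::rnorm(n, 0, 8)
        ch3[a$mask] <- 85 + stats::rnorm(n, 0, 6)
        rgb[, , 1] <- ch1; rgb[, , 2] <- ch2; rgb[, , 3] <- ch3
      }
    }
    rgb <- rgb + array(stats::rnorm(s * s * 3, 0, 5), c(s, s, 3))
    rgb <- round(pmin(pmax(rgb, 0), 255))
    storage.mode(rgb) <- "integer"

    annotations <- if (length(ann)) {
      dplyr::bind_rows(lapply(ann, function(a) {
        tibble::tibble(class = a$class,
                       x1 = unname(a$box[1]), y1 = unname(a$box[2]),
                       x2 = unname(a$box[3]), y2 = unname(a$box[4]))
      }))
    } else {
      tibble::tibble(class = character(0), x1 = numeric(0), y1 = numeric(0),
                     x2 = numeric(0), y2 = numeric(0))
    }

    structure(list(rgb = rgb, depth = depth_raster(noisy),
                   depth_clean = depth_clean, annotations = annotations,
                   true_gravity = g, camera = rig, config = config),
              class = "scene_pair")
  })
}

#' @export
print.scene_pair <- function(x, ...) {
  cat(sprintf("<scene_pair> %d x %d, %d weeds (%d grass, %d broadleaf), tilt %.2f deg\n",
              nrow(x$depth$values), ncol(x$depth$values), nrow(x$annotations),
              sum(x$annotations$class == "grass"),
              sum(x$annotations$class == "broadleaf"),
              acos(pmin(1, x$true_gravity[3])) * 180 / pi))
  invisible(x)
}

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

apply_raster_transform <- function(m, transform, k = 1L) {
  switch(transform,
         flip_h = m[, ncol(m):1, drop = FALSE],
         flip_v = m[nrow(m):1, , drop = FALSE],
         rot90k = {
           k <- k %% 4L
           for (i in seq_len(k)) m <- rot90_ccw(m)
           m
         },
         stop("unknown transform: ", transform))
}

apply_box_transform <- function(boxes, transform, width, height, k = 1L) {
  b <- as_box_matrix(boxes)
  if (nrow(b) == 0L) return(b)
  switch(transform,
         flip_h = cbind(x1 = width - b[, 3], y1 = b[, 2],
                        x2 = width - b[, 1], y2 = b[, 4]),
         flip_v = cbind(x1 = b[, 1], y1 = height - b[, 4],
                        x2 = b[, 3], y2 = height - b[, 2]),
         rot90k = {
           k <- k %% 4L
           for (i in seq_len(k)) {
             b <- cbind(x1 = b[, 2], y1 = width - b[, 3],
                        x2 = b[, 4], y2 = width - b[, 1])
             tmp <- width; width <- height; height <- tmp
           }
           b
         },
         stop("unknown transform: ", transform))
}

#' Rigid raster augmentation of a scene pair
#'
#' Applies one of the right-angle raster symmetries used for training-set
#' augmentation — horizontal flip, vertical flip, or `k` quarter-turn
#' rotations — consistently to the colour raster, depth raster, clean depth
#' and annotation boxes. The recorded gravity direction is unchanged (the
#' symmetries act about the optical axis).
#'
#' @param pair a `scene_pair` from [generate_scene()].
#' @param transform one of `"flip_h"`, `"flip_v"`, `"rot90k"`.
#' @param k number of quarter turns (counter-clockwise) for `"rot90k"`.
#' @return a transformed `scene_pair`.
#' @export
augment_pair <- function(pair, transform = c("flip_h", "flip_v", "rot90k"), k = 1L) {
  transform <- match.arg(transform)
  stopifnot(inherits(pair, "scene_pair"))
  h <- nrow(pair$depth$values); w <- ncol(pair$depth$values)
  tr <- function(m) apply_raster_transform(m, transform, k)
  d2 <- dim(tr(pair$rgb[, , 1]))
  rgb <- array(0L, c(d2, 3L))
  for (c in 1:3) rgb[, , c] <- tr(pair$rgb[, , c])
  boxes <- apply_box_transform(pair$annotations, transform, w, h, k)
  ann <- pair$annotations
  if (nrow(ann)) {
    ann$x1 <- unname(boxes[, 1]); ann$y1 <- unname(boxes[, 2])
    ann$x2 <- unname(boxes[, 3]); ann$y2 <- unname(boxes[, 4])
  }
  out <- pair
  out$rgb <- rgb
  out$depth <- depth_raster(tr(pair$depth$values))
  out$depth_clean <- tr(pair$depth_clean)
  out$annotations <- ann
  out
}

#' Write a scene pair to disk
#'
#' Emits `<id>_rgb.png` (8-bit colour), `<id>_depth.png` (16-bit, mm) and
#' `<id>.xml` (Pascal VOC) into `dir`.
#'
#' @param pair a `scene_pair`.
#' @param dir output directory (created if missing).
#' @param id basename stem for the three files.
#' @export
write_scene_pair <- function(pair, dir, id = "scene_001") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- dim(pair$depth$values)
  write_color_png(pair$rgb, file.path(dir, paste0(id, "_rgb.png")))
  write_depth_png(pair$depth, file.path(dir, paste0(id, "_depth.png")))
  write_voc_annotations(pair$annotations, file.path(dir, paste0(id, ".xml")),
                        image_size = c(s[2], s[1]),
                        filename = paste0(id, "_rgb.png"))
  invisible(file.path(dir, id))
}
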