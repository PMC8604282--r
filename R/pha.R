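#' Parameters for PHA depth recoding
#'
#' Controls the recoding of a metric depth raster into the three-channel PHA
#' image (Phase, Height above ground, Angle with gravity).
#'
#' @param l positive integer controlling the phase channel's uniqueness
#'   range `2*pi*l` (in mm). The default `l = 64` gives a uniqueness range of
#'   about 402 mm, so a rig ~700 mm above the canopy wraps the phase at least
#'   twice over the working range and the channel carries visible structure.
#'   Physically `l` is a property of the structured-light sensor; treated
#'   here as a configuration parameter.
#' @param d_max reference distance (mm) for the height channel, `H = d_max -
#'   d`. `NULL` (default) uses the per-image maximum distance; pass a fixed
#'   value for cross-image comparability.
#' @param normal_window odd window span (pixels) of the least-squares plane
#'   fit behind surface normals.
#' @param gravity_angle_threshold classification half-angle (degrees) used
#'   when splitting normals into gravity-parallel and gravity-perpendicular
#'   sets.
#' @param max_gravity_iters iteration cap for the gravity estimate.
#' @param literal_objective if `TRUE`, optimise the literal printed form of
#'   the gravity objective (parallel set drawn *orthogonal* to g); the
#'   default optimises the semantically consistent objective (parallel set
#'   drawn toward g). See the methods vignette.
#' @export
recode_params <- function(l = 64L, d_max = NULL, normal_window = 7L,
                          gravity_angle_threshold = 5,
                          max_gravity_iters = 20L,
                          literal_objective = FALSE) {
  if (length(l) != 1L || l < 1 || l != round(l)) stop("recode_params(): l must be a positive integer")
  if (normal_window < 3L || normal_window %% 2L == 0L) {
    stop("recode_params(): normal_window must be odd and >= 3")
  }
  structure(list(l = as.integer(l), d_max = d_max,
                 normal_window = as.integer(normal_window),
                 gravity_angle_threshold = gravity_angle_threshold,
                 max_gravity_iters = as.integer(max_gravity_iters),
                 literal_objective = literal_objective),
            class = "recode_params")
}

#' Phase channel of the PHA recoding
#'
#' Inverts the structured-light range equation `d = n * 2*pi*l + phi * l`
#' (with `n` the integer wrap count): `phi(i,j) = (d(i,j) mod 2*pi*l) / l`,
#' giving phase in radians on the half-open interval `[0, 2*pi)`. The phase
#' is periodic in depth with period `2*pi*l`.
#'
#' @param depth a hole-free [depth_raster()].
#' @param params a [recode_params()].
#' @return numeric matrix of phases in `[0, 2*pi)`.
#' @export
compute_phase <- function(depth, params = recode_params()) {
  stopifnot(inherits(depth, "depth_raster"))
  if (params$l == 0) stop("compute_phase(): l must be >= 1")
  (depth$values %% (2 * pi * params$l)) / params$l
}

#' Height-above-ground channel of the PHA recoding
#'
#' `H(i,j) = d_max - d(i,j)`: distance from the farthest surface (taken as
#' the ground) back toward the camera, in millimetres.
#'
#' @param depth a hole-free [depth_raster()].
#' @param d_max reference distance (mm); defaults to the per-image maximum.
#' @return numeric matrix of heights in `[0, d_max]`.
#' @export
compute_height <- function(depth, d_max = NULL) {
  stopifnot(inherits(depth, "depth_raster"))
  if (is.null(d_max)) d_max <- max(depth$values)
  if (d_max < max(depth$values)) {
    stop("compute_height(): d_max is below the observed maximum depth")
  }
  d_max - depth$values
}

# windowed box sums via integral images, clipped at borders
box_sum <- function(m, half) {
  h <- nrow(m); w <- ncol(m)
  ii <- matrix(0, h + 1, w + 1)
  ii[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(h) - half, 1L); r2 <- pmin(seq_len(h) + half, h)
  c1 <- pmax(seq_len(w) - half, 1L); c2 <- pmin(seq_len(w) + half, w)
  R1 <- rep(r1, w); R2 <- rep(r2 + 1L, w)
  C1 <- rep(c1, each = h); C2 <- rep(c2 + 1L, each = h)
  s <- ii[cbind(R2, C2)] - ii[cbind(R1, C2)] - ii[cbind(R2, C1)] + ii[cbind(R1, C1)]
  matrix(s, h, w)
}

#' Per-pixel surface normals from a depth raster
#'
#' Deprojects the raster to a 3D point cloud and fits, for every pixel, a
#' least-squares plane `Z = a X + b Y + c` over the window neighbourhood
#' (windowed moments via integral images); the normal is
#' `(-a, -b, 1)/norm`, i.e. oriented away from the camera (positive z, the
#' camera's down axis in a top-down rig). Rank-deficient neighbourhoods
#' (degenerate geometry) inherit the nearest well-conditioned estimate.
#'
#' @param depth a hole-free [depth_raster()].
#' @param rig a [camera_rig()] (depth intrinsics used).
#' @param window odd window span in pixels.
#' @return array `H x W x 3` of unit normals.
#' @export
estimate_normals <- function(depth, rig, window = 5L) {
  stopifnot(inherits(depth, "depth_raster"))
  if (!all(depth$valid)) stop("estimate_normals(): depth must be hole-free; run fill_holes() first")
  d <- depth$values
  h <- nrow(d); w <- ncol(d)
  K <- rig$K_depth
  u <- matrix(rep(0:(w - 1), each = h), h, w)
  v <- matrix(rep(0:(h - 1), w), h, w)
  X <- (u - K$cx) / K$fx * d
  Y <- (v - K$cy) / K$fy * d
  Z <- d
  half <- (as.integer(window) - 1L) %/% 2L
  n <- box_sum(matrix(1, h, w), half)
  sx <- box_sum(X, half); sy <- box_sum(Y, half); sz <- box_sum(Z, half)
  sxx <- box_sum(X * X, half); syy <- box_sum(Y * Y, half)
  sxy <- box_sum(X * Y, half); sxz <- box_sum(X * Z, half); syz <- box_sum(Y * Z, half)
  cxx <- sxx - sx * sx / n; cyy <- syy - sy * sy / n
  cxy <- sxy - sx * sy / n; cxz <- sxz - sx * sz / n; cyz <- syz - sy * sz / n
  det <- cxx * cyy - cxy * cxy
  ok <- is.finite(det) & det > 1e-9 * pmax(cxx * cyy, 1e-12)
  a <- (cyy * cxz - cxy * cyz) / det
  b <- (cxx * cyz - cxy * cxz) / det
  nx <- -a; ny <- -b; nz <- matrix(1, h, w)
  nrm <- sqrt(nx^2 + ny^2 + 1)
  normals <- array(c(nx / nrm, ny / nrm, nz / nrm), c(h, w, 3))
  if (any(!ok)) {
    # fall back to the nearest well-conditioned estimate
    bad <- which(!ok); good <- which(ok)
    if (!length(good)) stop("estimate_normals(): no well-conditioned neighbourhood")
    br <- (bad - 1L) %% h; bc <- (bad - 1L) %/% h
    gr <- (good - 1L) %% h; gc <- (good - 1L) %/% h
    for (i in seq_along(bad)) {
      j <- good[which.min((gr - br[i])^2 + (gc - bc[i])^2)]
      jr <- (j - 1L) %% h + 1L; jc <- (j - 1L) %/% h + 1L
      ir <- br[i] + 1L; ic <- bc[i] + 1L
      normals[ir, ic, ] <- normals[jr, jc, ]
    }
  }
  normals
}

#' Estimate the gravity direction from surface normals
#'
#' Iterative estimate in the spirit of geocentric depth encodings:
#' initialise `g` to the camera's down axis (the optical axis `(0, 0, 1)` of
#' a top-down rig), then repeatedly (i) classify normals into a
#' gravity-parallel set N1 (angle to `g` or `-g` below the threshold) and a
#' gravity-perpendicular set N2 (angle to the plane orthogonal to `g` below
#' the threshold), and (ii) update `g` as the extremal eigenvector of the
#' scatter-difference matrix `S1 - S2` (`Sk` the sum of outer products of the
#' set's normals): the maximal eigenvector minimises
#' `sum_{N1} sin^2(theta) + sum_{N2} cos^2(theta)`, drawing `g` toward the
#' parallel set and orthogonal to the perpendicular set. With
#' `literal_objective = TRUE` the minimal eigenvector is taken instead,
#' optimising the objective exactly as printed in the source formulation.
#' Iteration stops when `g` moves less than 0.1 degrees.
#'
#' @param normals `H x W x 3` array (or `n x 3` matrix) of unit normals.
#' @param params a [recode_params()].
#' @return a `gravity_estimate`: list with unit vector `g` (sign fixed to a
#'   non-negative dot product with the camera down axis), set sizes
#'   `n_parallel`, `n_perpendicular`, `iterations`, the final `objective`,
#'   and a `converged` flag.
#' @export
estimate_gravity <- function(normals, params = recode_params()) {
  if (length(dim(normals)) == 3L) {
    normals <- matrix(normals, ncol = 3)
  }
  down <- c(0, 0, 1)
  g <- down
  thr <- cos(params$gravity_angle_threshold * pi / 180)
  iter <- 0L; converged <- FALSE
  n1 <- n2 <- 0L; objective <- NA_real_
  repeat {
    iter <- iter + 1L
    dt <- abs(as.numeric(normals %*% g))       # |cos(angle to g)|
    par_set <- dt > thr                        # near parallel (either sign)
    perp_set <- dt < sqrt(max(0, 1 - thr^2))   # near the orthogonal plane
    n1 <- sum(par_set); n2 <- sum(perp_set)
    if (n1 + n2 == 0L) stop("estimate_gravity(): no normals within the angle threshold")
    S1 <- if (n1) crossprod(normals[par_set, , drop = FALSE]) else matrix(0, 3, 3)
    S2 <- if (n2) crossprod(normals[perp_set, , drop = FALSE]) else matrix(0, 3, 3)
    eg <- eigen(S1 - S2, symmetric = TRUE)
    g_new <- eg$vectors[, if (params$literal_objective) 3 else 1]
    if (sum(g_new * down) < 0) g_new <- -g_new
    ct <- as.numeric(normals %*% g_new)
    objective <- sum(1 - ct[par_set]^2) + sum(ct[perp_set]^2)
    ang <- acos(pmin(1, abs(sum(g_new * g)))) * 180 / pi
    g <- g_new
    if (ang < 0.1) { converged <- TRUE; break }
    if (iter >= params$max_gravity_iters) break
  }
  if (!converged) warning("estimate_gravity(): not converged after ",
                          iter, " iterations; returning best iterate")
  structure(list(g = g, n_parallel = n1, n_perpendicular = n2,
                 iterations = iter, objective = objective,
                 converged = converged),
            class = "gravity_estimate")
}

#' Angle between each surface normal and the gravity direction
#'
#' `theta(i,j) = arccos(clamp(n(i,j) . g, -1, 1))` in degrees, in
#' `[0, 180]`. Normals keep their camera-based orientation, so up- and
#' down-facing surfaces remain distinguishable.
#'
#' @param normals `H x W x 3` array of unit normals.
#' @param g unit gravity vector.
#' @return numeric matrix of angles in degrees.
#' @export
compute_gravity_angle <- function(normals, g) {
  stopifnot(abs(sum(g^2) - 1) < 1e-6)
  d <- dim(normals)
  ct <- matrix(normals, ncol = 3) %*% g
  matrix(acos(pmin(1, pmax(-1, ct))) * 180 / pi, d[1], d[2])
}

#' Recode a depth raster into a three-channel PHA image
#'
#' Assembles the phase, height and gravity-angle channels and an 8-bit
#' quantized raster structurally parallel to an RGB image, using the fixed
#' linear maps `phase * 255 / (2*pi)`, `height * 255 / d_max`,
#' `angle * 255 / 180`, channel order (P, H, A).
#'
#' @param depth a hole-free [depth_raster()].
#' @param rig a [camera_rig()].
#' @param params a [recode_params()].
#' @return a `pha_image`: list with float channels `phase` (radians),
#'   `height` (mm), `angle` (degrees), the `quantized` integer array
#'   `H x W x 3` (0..255), the `gravity` estimate, and `d_max` used.
#' @export
recode_to_pha <- function(depth, rig, params = recode_params()) {
  stopifnot(inherits(depth, "depth_raster"))
  if (!all(depth$valid)) stop("recode_to_pha(): depth must be hole-free; run fill_holes() first")
  phase <- compute_phase(depth, params)
  d_max <- if (is.null(params$d_max)) max(depth$values) else params$d_max
  height <- compute_height(depth, d_max)
  normals <- estimate_normals(depth, rig, params$normal_window)
  gravity <- estimate_gravity(normals, params)
  angle <- compute_gravity_angle(normals, gravity$g)
  q <- array(0L, c(dim(depth$values), 3L))
  q[, , 1] <- round(phase * 255 / (2 * pi))
  q[, , 2] <- round(height * 255 / max(d_max, 1e-9))
  q[, , 3] <- round(angle * 255 / 180)
  storage.mode(q) <- "integer"
  structure(list(phase = phase, height = height, angle = angle,
                 quantized = q, gravity = gravity, d_max = d_max),
            class = "pha_image")
}

#' @export
print.pha_image <- function(x, ...) {
  cat(sprintf("<pha_image> %d x %d, d_max = %.0f mm, gravity tilt = %.2f deg\n",
              nrow(x$phase), ncol(x$phase), x$d_max,
              acos(pmin(1, abs(x$gravity$g[3]))) * 180 / pi))
  invisible(x)
}

#' Shannon entropy of an 8-bit raster
#'
#' Entropy of the 256-bin intensity histogram, `-sum p_k log2 p_k`, averaged
#' over channels for multi-channel rasters; ranges from 0 (constant image)
#' to 8 bits (uniform use of all 256 values).
#'
#' @param raster integer matrix or `H x W x C` array with values 0..255.
#' @return entropy in bits.
#' @export
image_entropy <- function(raster) {
  if (length(raster) == 0L) stop("image_entropy(): empty raster")
  if (any(raster < 0 | raster > 255)) stop("image_entropy(): values must be in 0..255")
  chan_ent <- function(m) {
    p <- tabulate(as.integer(m) + 1L, 256L)
    p <- p / sum(p)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  if (length(dim(raster)) == 3L) {
    mean(vapply(seq_len(dim(raster)[3]), function(c) chan_ent(raster[, , c]), numeric(1)))
  } else {
    chan_ent(raster)
  }
}

#' Render a depth raster as an 8-bit greyscale image
#'
#' Fixed linear map of the sensor's 16-bit millimetre range onto 0..255 (the
#' rendering a 16-bit depth PNG gets in ordinary image tooling). Because a
#' field scene occupies a few hundred millimetres of a 65-metre encoding
#' range, the rendering collapses onto a handful of grey levels — the flat,
#' low-information look of raw depth that PHA recoding is designed to fix.
#' Pass `max_value = NULL` to min-max normalise per image instead.
#'
#' @param depth a [depth_raster()].
#' @param max_value full-scale depth (mm) of the fixed map; default 65535.
#' @export
depth_to_8bit <- function(depth, max_value = 65535) {
  v <- depth$values
  if (is.null(max_value)) {
    rng <- range(v)
    if (diff(rng) == 0) return(matrix(0L, nrow(v), ncol(v)))
    m <- round((v - rng[1]) / diff(rng) * 255)
  } else {
    m <- round(pmin(v, max_value) / max_value * 255)
  }
  storage.mode(m) <- "integer"
  m
}
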