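test_that("phase inverts the range equation onto [0, 2*pi)", {
  l <- 100L
  pr <- recode_params(l = l)
  d <- depth_raster(matrix(c(1e-9, 200 * pi, 100 * pi, 50 * pi), 2, 2))
  ph <- compute_phase(d, pr)
  expect_equal(ph[1, 1], 1e-9 / 100)        # d ~ 0 -> phase ~ 0
  expect_equal(ph[2, 1], 0)                 # exactly one wrap -> 0 (half-open)
  expect_equal(ph[1, 2], pi)                # half the uniqueness range
  expect_equal(ph[2, 2], pi / 2)
  expect_error(compute_phase(d, structure(list(l = 0), class = "recode_params")), "l must be")
})

test_that("phase is periodic in depth with period 2*pi*l", {
  pr <- recode_params(l = 64L)
  period <- 2 * pi * 64
  d0 <- matrix(runif(64, 1, 4000), 8, 8)
  for (k in 1:3) {
    expect_equal(compute_phase(depth_raster(d0 + k * period), pr),
                 compute_phase(depth_raster(d0), pr), tolerance = 1e-9)
  }
})

test_that("height channel is d_max minus depth with validation", {
  d <- depth_raster(matrix(c(2000, 1500, 700, 1), 2, 2))
  H <- compute_height(d, 2000)
  expect_equal(H[1, 1], 0)
  expect_equal(H[2, 1], 500)
  expect_error(compute_height(d, 1000), "below the observed maximum")
  # constant-depth scene with per-image d_max is all-zero height
  expect_true(all(compute_height(depth_raster(matrix(700, 4, 4))) == 0))
})

test_that("surface normals recover planes to half a degree", {
  rig <- scene_rig(64L)
  plane <- depth_raster(matrix(700, 64, 64))
  n <- estimate_normals(plane, rig, 5L)
  ang <- acos(pmin(1, abs(matrix(n, ncol = 3) %*% c(0, 0, 1)))) * 180 / pi
  expect_lt(max(ang), 0.5)

  # plane tilted 10 degrees about x: Z = 700 + tan(10 deg) * Y
  K <- rig$K_depth
  v <- matrix(rep(0:63, 64), 64, 64)
  ry <- (v - K$cy) / K$fy
  tilted <- depth_raster(700 / (1 - tan(10 * pi / 180) * ry))
  n10 <- estimate_normals(tilted, rig, 5L)
  a10 <- acos(pmin(1, abs(matrix(n10, ncol = 3) %*% c(0, 0, 1)))) * 180 / pi
  expect_true(all(abs(a10 - 10) < 0.5))

  # window size does not matter on a noiseless plane
  n7 <- estimate_normals(tilted, rig, 7L)
  expect_equal(n7, n10, tolerance = 1e-6)
})

test_that("gravity estimation handles canonical normal fields", {
  pr <- recode_params()
  # single direction: exact recovery
  nn <- array(rep(c(0, 0, 1), each = 16), c(4, 4, 3))
  g <- estimate_gravity(nn, pr)
  expect_equal(g$g, c(0, 0, 1))
  expect_true(g$converged)

  # 50/50 split between floor normals (0,0,1) and wall normals (1,0,0):
  # the floor set dominates alignment and g stays on the axis
  N <- rbind(matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE),
             matrix(rep(c(1, 0, 0), 50), ncol = 3, byrow = TRUE))
  g2 <- estimate_gravity(array(N, c(10, 10, 3)), pr)
  expect_lt(acos(min(1, abs(sum(g2$g * c(0, 0, 1))))) * 180 / pi, 0.5)
  expect_equal(g2$n_parallel + g2$n_perpendicular, 100)
})

test_that("gravity recovery on synthetic scenes is within 2 degrees (median)", {
  errs <- vapply(1:20, function(sd) {
    p <- generate_scene(scene_config(image_size = 96L, seed = sd))
    filled <- fill_holes(p$depth)
    nn <- estimate_normals(filled, p$camera, 7L)
    g <- suppressWarnings(estimate_gravity(nn, recode_params()))
    acos(min(1, abs(sum(g$g * p$true_gravity)))) * 180 / pi
  }, numeric(1))
  expect_lte(median(errs), 2)
})

test_that("gravity angle raster hits the canonical values", {
  g <- c(0, 0, 1)
  nn <- array(0, c(1, 3, 3))
  nn[1, 1, ] <- g            # parallel
  nn[1, 2, ] <- c(1, 0, 0)   # perpendicular
  nn[1, 3, ] <- -g           # antiparallel
  th <- compute_gravity_angle(nn, g)
  expect_equal(as.vector(th), c(0, 90, 180))
  expect_error(compute_gravity_angle(nn, c(0, 0, 2)))
})

test_that("recode_to_pha assembles quantized channels deterministically", {
  p <- small_scene(7, 64L)
  filled <- fill_holes(p$depth)
  pha <- suppressWarnings(recode_to_pha(filled, p$camera))
  expect_identical(dim(pha$quantized), c(64L, 64L, 3L))
  expect_true(all(pha$quantized >= 0 & pha$quantized <= 255))
  expect_true(all(is.finite(pha$phase)) && all(is.finite(pha$angle)))
  expect_true(all(pha$phase >= 0 & pha$phase < 2 * pi))
  expect_true(all(pha$height >= 0 & pha$height <= pha$d_max))
  expect_true(all(pha$angle >= 0 & pha$angle <= 180))
  # quantization maps are the fixed linear ones
  expect_equal(pha$quantized[, , 1], round(pha$phase * 255 / (2 * pi)))
  expect_equal(pha$quantized[, , 2], round(pha$height * 255 / pha$d_max))
  expect_equal(pha$quantized[, , 3], round(pha$angle * 255 / 180))
  # deterministic
  expect_identical(pha, suppressWarnings(recode_to_pha(filled, p$camera)))
  # constant-depth plane: per-image d_max makes the H channel all zero
  flat <- depth_raster(matrix(700, 32, 32))
  pf <- suppressWarnings(recode_to_pha(flat, scene_rig(32L)))
  expect_true(all(pf$quantized[, , 2] == 0))
  # hole-free precondition enforced
  expect_error(recode_to_pha(p$depth, p$camera), "hole-free")
})

test_that("image entropy matches closed forms", {
  expect_equal(image_entropy(matrix(7L, 10, 10)), 0)
  two <- matrix(c(0L, 255L), 16, 16)
  expect_equal(image_entropy(two), 1)
  expect_equal(image_entropy(matrix(0:255, 16, 16)), 8)
  expect_error(image_entropy(matrix(numeric(0), 0, 0)), "empty")
  expect_error(image_entropy(matrix(300, 2, 2)), "0..255")
})

test_that("PHA images carry more information than 8-bit depth renderings", {
  wins <- vapply(1:20, function(sd) {
    p <- generate_scene(scene_config(image_size = 64L, seed = sd))
    filled <- fill_holes(p$depth)
    pha <- suppressWarnings(recode_to_pha(filled, p$camera))
    image_entropy(pha$quantized) > image_entropy(depth_to_8bit(filled))
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
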