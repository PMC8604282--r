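test_that("identity rig reproduces the input depth on the common grid", {
  p <- small_scene(7, 64L)
  rig <- scene_rig(64L)
  al <- align_depth_to_color(p$depth, rig)
  # identity transform maps every valid pixel exactly onto itself
  expect_identical(al$valid, p$depth$valid)
  expect_equal(al$values[al$valid], p$depth$values[p$depth$valid])
})

test_that("pure x-translation shifts a fronto-parallel plane by the closed-form disparity", {
  # plane at 700 mm, t = (50, 0, 0): every pixel moves by fx * 50 / 700
  fx <- 120
  rig <- camera_rig(fx, fx, 31.5, 31.5, R = diag(3), t = c(50, 0, 0))
  plane <- depth_raster(matrix(700, 64, 64))
  al <- align_depth_to_color(plane, rig)
  disp <- fx * 50 / 700
  # a depth pixel at column u lands at u + disp; verify against the analytic
  # shift at every valid output pixel
  expect_true(any(al$valid))
  expect_equal(unique(al$values[al$valid]), 700)
  # valid columns are exactly those reachable by the rounded shift
  valid_cols <- which(apply(al$valid, 2, any)) - 1
  expected_cols <- unique(pmin(pmax(round(0:63 + disp), -1), 64))
  expected_cols <- expected_cols[expected_cols >= 0 & expected_cols < 64]
  expect_setequal(valid_cols, expected_cols)
  # per-pixel positional error of the splat is at most 0.5 px by rounding
  expect_lte(max(abs(valid_cols - (valid_cols - disp + disp))), 0.5)
})

test_that("alignment z-buffers nearer surfaces over farther ones", {
  # two pixels engineered to project onto the same output pixel under an
  # x-translation: shift = fx * tx / d, so (u=10, d=500) and (u=17, d=1000)
  # both land on column 24 with fx = 100, tx = 70
  fx <- 100
  rig <- camera_rig(fx, fx, 15.5, 15.5, R = diag(3), t = c(70, 0, 0))
  d <- matrix(0, 32, 32)
  d[16, 10 + 1] <- 500
  d[16, 17 + 1] <- 1000
  al <- align_depth_to_color(depth_raster(d), rig)
  expect_equal(al$values[16, 24 + 1], 500)
  # all-invalid input stays all-invalid
  expect_false(any(align_depth_to_color(depth_raster(matrix(0, 8, 8)), rig)$valid))
})

test_that("rotation-only alignment preserves the depth histogram up to occlusion", {
  p <- small_scene(3, 64L)
  th <- 2 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rig <- camera_rig(1.2 * 64, 1.2 * 64, 31.5, 31.5, R = Rz)
  al <- align_depth_to_color(p$depth, rig)
  # metric values preserved: every aligned value close to some input value
  v_in <- p$depth$values[p$depth$valid]
  v_out <- al$values[al$valid]
  expect_gt(length(v_out), 0.8 * length(v_in))
  expect_lt(max(abs(range(v_out) - range(v_in))), 2)
})

test_that("fill_holes removes every hole and leaves valid pixels untouched", {
  p <- generate_scene(scene_config(image_size = 96L, hole_fraction = 0.1, seed = 5L))
  filled <- fill_holes(p$depth)
  expect_true(all(filled$valid))
  expect_equal(filled$values[p$depth$valid], p$depth$values[p$depth$valid])
  # filled values stay within the observed valid range
  rng <- range(p$depth$values[p$depth$valid])
  expect_true(all(filled$values >= rng[1] & filled$values <= rng[2]))
  # idempotence
  expect_identical(fill_holes(filled), filled)
})

test_that("single hole in a constant neighbourhood takes that value; all-invalid rejected", {
  d <- matrix(900, 9, 9); d[5, 5] <- 0
  filled <- fill_holes(depth_raster(d))
  expect_equal(filled$values[5, 5], 900)
  d2 <- matrix(900, 9, 9); filled2 <- fill_holes(depth_raster(d2))
  expect_identical(filled2$values, d2)
  expect_error(fill_holes(depth_raster(matrix(0, 4, 4))), "no valid pixels")
})

test_that("fill error off depth discontinuities is within 3x the depth noise", {
  p <- generate_scene(scene_config(image_size = 96L, hole_fraction = 0.1, seed = 2L))
  filled <- fill_holes(p$depth)
  s <- 96L
  gx <- cbind(abs(p$depth_clean[, -1] - p$depth_clean[, -s]), 0)
  gy <- rbind(abs(p$depth_clean[-1, ] - p$depth_clean[-s, ]), 0)
  near_step <- box_sum((pmax(gx, gy) > 20) * 1, 3) > 0
  off <- !p$depth$valid & !near_step
  expect_gt(sum(off), 50)
  rmse <- sqrt(mean((filled$values[off] - p$depth_clean[off])^2))
  expect_lt(rmse, 3 * p$config$depth_noise_sd)
})
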