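mk_det <- function(image_id, class, box, score, branch) {
  tibble::tibble(image_id = image_id, class = class, x1 = box[1], y1 = box[2],
                 x2 = box[3], y2 = box[4], score = score, branch = branch)
}

test_that("weight validation enforces the simplex constraint", {
  expect_error(ensemble_weights(-0.1, 0.5))
  expect_error(ensemble_weights(0.6, 0.6))
  w <- ensemble_weights(0.4, 0.3)
  expect_equal(w$gamma, 0.3)
})

test_that("the fused score is the weighted branch combination", {
  box <- c(10, 10, 30, 30)
  d <- dplyr::bind_rows(mk_det("a", "grass", box, 0.9, "rgb"),
                        mk_det("a", "grass", box, 0.6, "pha"),
                        mk_det("a", "grass", box, 0.3, "corr"))
  f <- fuse_detections(d, ensemble_weights(0.4, 0.3))
  expect_identical(nrow(f), 1L)
  expect_equal(f$score, 0.4 * 0.9 + 0.3 * 0.6 + 0.3 * 0.3) # 0.63
  expect_equal(unlist(f[1, c("x1", "y1", "x2", "y2")], use.names = FALSE), box)
})

test_that("corner weights reproduce single branches exactly", {
  set.seed(4)
  d <- dplyr::bind_rows(lapply(c("rgb", "pha", "corr"), function(br) {
    b <- random_boxes(4, 100)
    tibble::tibble(image_id = "img", class = sample(c("grass", "broadleaf"), 4, TRUE),
                   x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4],
                   score = runif(4, 0.2, 0.9), branch = br)
  }))
  for (w in list(c(1, 0), c(0, 1), c(0, 0))) {
    br <- c("rgb", "pha", "corr")[c(w[1] == 1, w[2] == 1, w[1] + w[2] == 0)]
    f <- fuse_detections(d, ensemble_weights(w[1], w[2]))
    ref <- d[d$branch == br, ]
    ref <- ref[order(ref$image_id, ref$class, -ref$score), ]
    expect_equal(f$score, ref$score)
    expect_equal(f[, c("x1", "y1", "x2", "y2")], ref[, c("x1", "y1", "x2", "y2")])
  }
})

test_that("disjoint single-branch boxes stay separate with down-weighted scores", {
  d <- dplyr::bind_rows(mk_det("a", "grass", c(0, 0, 10, 10), 0.8, "rgb"),
                        mk_det("a", "grass", c(40, 40, 50, 50), 0.8, "pha"),
                        mk_det("a", "grass", c(80, 80, 90, 90), 0.8, "corr"))
  f <- fuse_detections(d, ensemble_weights(0.5, 0.3))
  expect_identical(nrow(f), 3L)
  expect_setequal(round(f$score, 10), round(0.8 * c(0.5, 0.3, 0.2), 10))
})

test_that("fused scores are linear in branch scores and stay within [0, 1]", {
  box <- c(5, 5, 25, 25)
  w <- ensemble_weights(0.25, 0.35)
  set.seed(9)
  for (rep in 1:20) {
    s <- runif(3)
    d <- dplyr::bind_rows(mk_det("a", "grass", box, s[1], "rgb"),
                          mk_det("a", "grass", box, s[2], "pha"),
                          mk_det("a", "grass", box, s[3], "corr"))
    f <- fuse_detections(d, w)
    expect_equal(f$score, 0.25 * s[1] + 0.35 * s[2] + 0.4 * s[3])
    expect_true(f$score >= 0 && f$score <= 1)
  }
})

test_that("the weight grid has exactly 231 feasible points at step 0.05", {
  # constructed validation case: rgb branch perfect, the others empty
  ann <- tibble::tibble(class = c("grass", "broadleaf"),
                        x1 = c(5, 40), y1 = c(5, 40), x2 = c(20, 60), y2 = c(20, 60))
  dets <- dplyr::bind_rows(
    mk_det("v1", "grass", c(5, 5, 20, 20), 0.95, "rgb"),
    mk_det("v1", "broadleaf", c(40, 40, 60, 60), 0.9, "rgb"))
  gs <- grid_search_weights(dets, list(v1 = ann), list(v1 = c(100, 100)), step = 0.05)
  expect_identical(nrow(gs$surface), 231L)
  expect_true(all(gs$surface$score >= 0 & gs$surface$score <= 100))
  # the rgb corner attains the optimum and the returned best matches it;
  # mAP is rank-based, so every grid point that keeps the rgb detections
  # scores 100 and the tie is broken toward small alpha/beta
  corner <- gs$surface$score[gs$surface$alpha == 1 & gs$surface$beta == 0]
  expect_equal(corner, 100)
  expect_equal(gs$best_score, 100)
  expect_equal(gs$best_score,
               max(gs$surface$score))
  # with the rgb branch silenced (alpha = 0, gamma = 0 at beta = 1) there is
  # nothing to detect and the score collapses
  expect_equal(gs$surface$score[gs$surface$alpha == 0 & gs$surface$beta == 1], 0)
  # invariant to validation-set ordering
  gs2 <- grid_search_weights(dets[sample(nrow(dets)), ], list(v1 = ann),
                             list(v1 = c(100, 100)), step = 0.05)
  expect_equal(gs2$best, gs$best)
  expect_equal(dplyr::arrange(gs2$surface, alpha, beta),
               dplyr::arrange(gs$surface, alpha, beta))
  expect_error(grid_search_weights(dets, list(), list(), step = 0.05), "empty")
  expect_error(grid_search_weights(dets, list(v1 = ann), list(v1 = c(100, 100)),
                                   step = 0.03), "divide")
})

test_that("grid search under a score-sensitive metric rewards the perfect branch", {
  # IoG applies a score cutoff, so diluting weight away from the perfect rgb
  # branch eventually drops its detections below threshold: the argmax set
  # is exactly the weights keeping alpha * score above the cutoff
  ann <- tibble::tibble(class = "grass", x1 = 5, y1 = 5, x2 = 20, y2 = 20)
  dets <- mk_det("v1", "grass", c(5, 5, 20, 20), 1, "rgb")
  gs <- grid_search_weights(dets, list(v1 = ann), list(v1 = c(64, 64)),
                            step = 0.05, metric = "iog")
  expect_equal(gs$best_score, 100)
  expect_gte(gs$best$alpha, 0.5)
  surf <- gs$surface
  expect_true(all(surf$score[surf$alpha < 0.5] == 0))
  expect_true(all(surf$score[surf$alpha >= 0.5] == 100))
})
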