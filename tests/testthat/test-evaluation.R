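mk_dets <- function(boxes, scores, class = "grass", image_id = "img", branch = "rgb") {
  b <- as_box_matrix(boxes)
  tibble::tibble(image_id = image_id, class = class,
                 x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4],
                 score = scores, branch = branch)
}
mk_ann <- function(boxes, class = "grass") {
  b <- as_box_matrix(boxes)
  tibble::tibble(class = class, x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4])
}

test_that("greedy matching assigns each ground truth at most once", {
  gt <- c(10, 10, 30, 30)
  # perfect single match
  m <- match_detections(mk_dets(gt, 0.9), list(img = mk_ann(gt)))
  expect_identical(m$tp, TRUE)
  # two detections on one gt: only the higher-scored one is TP
  m2 <- match_detections(mk_dets(rbind(gt, gt + 1), c(0.8, 0.9)),
                         list(img = mk_ann(gt)))
  expect_identical(m2$tp[order(-m2$score)], c(TRUE, FALSE))
  # no ground truth: everything is a false positive
  m3 <- match_detections(mk_dets(gt, 0.9), list(img = mk_ann(gt)[0, ]))
  expect_identical(m3$tp, FALSE)
  # class-aware: a grass detection cannot match a broadleaf gt
  m4 <- match_detections(mk_dets(gt, 0.9, class = "grass"),
                         list(img = mk_ann(gt, class = "broadleaf")))
  expect_identical(m4$tp, FALSE)
})

test_that("average precision hits its closed-form corners", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE), 3), 100)
  expect_equal(average_precision(c(FALSE, FALSE), 5), 0)
  expect_warning(ap0 <- average_precision(TRUE, 0), "undefined")
  expect_true(is.na(ap0))
  # hand case: TP FP TP FP TP with 3 gts
  tp <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  # envelope precisions at the three recall steps: 1, 2/3, 3/5
  expect_equal(average_precision(tp, 3), mean(c(1, 2 / 3, 3 / 5)) * 100,
               tolerance = 1e-9)
})

test_that("AP equals the exhaustive threshold-sweep oracle on random instances", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(1:10, 1)
    n_gt <- sample(1:6, 1)
    tp <- runif(n) < 0.5
    if (sum(tp) > n_gt) tp[which(tp)][-seq_len(n_gt)] <- FALSE
    expect_equal(average_precision(tp, n_gt), ap_oracle(tp, n_gt),
                 tolerance = 1e-9)
  }
})

test_that("AP depends on score ranks only", {
  gt <- rbind(c(0, 0, 10, 10), c(30, 30, 50, 50))
  d <- mk_dets(rbind(c(0, 0, 10, 10), c(31, 31, 50, 50), c(70, 70, 80, 80)),
               c(0.9, 0.5, 0.2))
  ann <- list(img = mk_ann(gt))
  # (no broadleaf ground truth here: the class-exclusion warning is expected)
  e1 <- suppressWarnings(evaluate_detections(d, ann, c(100, 100)))
  d2 <- d; d2$score <- d$score * 0.13
  e2 <- suppressWarnings(evaluate_detections(d2, ann, c(100, 100), score_threshold = 0))
  expect_equal(e1$per_class$ap, e2$per_class$ap)
})

test_that("IoG measures ground-truth coverage by area", {
  gt <- c(10, 10, 30, 30)          # 400 px
  ann <- list(img = mk_ann(gt))
  sz <- list(img = c(64, 64))
  # exact tiling -> 100%
  expect_equal(iog(mk_dets(gt, 0.9), ann, sz), 100)
  # no detections -> 0%
  expect_equal(iog(mk_dets(gt, 0.9)[0, ], ann, sz), 0)
  # covering exactly half the gt box -> 50%
  expect_equal(iog(mk_dets(c(10, 10, 20, 30), 0.9), ann, sz), 50)
  # class-agnostic by default: a broadleaf detection still covers grass gt
  expect_equal(iog(mk_dets(gt, 0.9, class = "broadleaf"), ann, sz), 100)
  # below-threshold detections are ignored
  expect_equal(iog(mk_dets(gt, 0.3), ann, sz, score_threshold = 0.5), 0)
  # growing the detection box never decreases IoG
  vals <- vapply(seq(10, 40, 5), function(x2) {
    iog(mk_dets(c(10, 10, x2, 30), 0.9), ann, sz)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(iog(mk_dets(gt, 0.9), list(img = mk_ann(gt)[0, ]), sz), "empty")
})

test_that("evaluate_detections fills a consistent report", {
  gts <- list(a = mk_ann(rbind(c(0, 0, 20, 20), c(40, 40, 60, 60)),
                         c("grass", "broadleaf")),
              b = mk_ann(c(10, 10, 40, 40), "grass"))
  perfect <- dplyr::bind_rows(
    mk_dets(c(0, 0, 20, 20), 0.95, "grass", "a"),
    mk_dets(c(40, 40, 60, 60), 0.9, "broadleaf", "a"),
    mk_dets(c(10, 10, 40, 40), 0.99, "grass", "b"))
  ev <- evaluate_detections(perfect, gts, c(80, 80))
  expect_equal(ev$map, 100)
  expect_equal(ev$iog, 100)
  expect_equal(ev$map, mean(ev$per_class$ap))
  # a disjoint false positive cannot raise AP or IoG
  fp <- dplyr::bind_rows(perfect, mk_dets(c(70, 0, 79, 10), 0.97, "grass", "b"))
  ev2 <- evaluate_detections(fp, gts, c(80, 80))
  expect_lte(ev2$map, ev$map)
  expect_equal(ev2$iog, ev$iog)
  # id mismatch reported
  expect_error(evaluate_detections(mk_dets(c(0, 0, 5, 5), 1, image_id = "zz"),
                                   gts, c(80, 80)), "zz")
  # tidy / glance accessors
  td <- generics::tidy(ev)
  expect_identical(td$class, c("grass", "broadleaf"))
  gl <- generics::glance(ev)
  expect_identical(names(gl), c("map", "iog", "iou_threshold", "score_threshold"))
})
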