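test_that("box delta encoding matches the closed form and round-trips", {
  expect_equal(unname(encode_box_deltas(c(75, 75, 125, 125), c(75, 75, 125, 125))),
               matrix(0, 1, 4))
  # anchor centre (100,100) size 50x50; gt centre (105,110) size 100x25
  d <- encode_box_deltas(c(55, 97.5, 155, 122.5), c(75, 75, 125, 125))
  expect_equal(unname(d), matrix(c(0.1, 0.2, log(2), log(0.5)), 1), tolerance = 1e-12)

  set.seed(1)
  for (i in 1:100) {
    a <- random_boxes(1); b <- random_boxes(1)
    expect_equal(unname(decode_box_deltas(encode_box_deltas(b, a), a)),
                 unname(b), tolerance = 1e-9)
  }
  expect_error(encode_box_deltas(c(0, 0, 0, 5), c(0, 0, 5, 5)), "positive extent")
})

test_that("smooth L1 matches its branch values and is C1 at the joint", {
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(0.5), 0.125)
  expect_equal(smooth_l1(2), 1.5)
  expect_equal(smooth_l1(-2), 1.5)
  # continuity and derivative continuity at |x| = 1
  eps <- 1e-8
  expect_equal(smooth_l1(1 - eps), smooth_l1(1 + eps), tolerance = 1e-6)
  expect_equal((smooth_l1(1 + eps) - smooth_l1(1 - eps)) / (2 * eps), 1,
               tolerance = 1e-4)
})

test_that("Hadamard fusion is exact, commutative, and shape-checked", {
  set.seed(2)
  a <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  b <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  f <- hadamard_fuse(a, b)
  # scalar-loop oracle
  for (i in sample(length(a), 25)) expect_identical(f[i], a[i] * b[i])
  expect_identical(hadamard_fuse(a, b), hadamard_fuse(b, a))
  expect_identical(hadamard_fuse(a, array(1, dim(a))), a)
  expect_true(all(hadamard_fuse(a, array(0, dim(a))) == 0))
  expect_error(hadamard_fuse(a, array(0, c(5, 4, 3))), "shape")
})

test_that("anchor assignment follows the two positive rules", {
  anchors <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30), c(50, 50, 60, 60))
  gts <- rbind(c(0, 0, 10, 10),      # identical to anchor 1
               c(21, 21, 29, 31))    # best overlap anchor 2, below 0.7
  asg <- assign_anchor_labels(anchors, gts)
  expect_equal(asg$labels[1], 1)     # IoU = 1
  expect_equal(asg$labels[2], 1)     # highest-overlap rule
  expect_equal(asg$labels[3], 0)     # disjoint -> negative
  expect_equal(asg$matched[1:2], c(1L, 2L))
  # every gt has at least one positive anchor
  set.seed(3)
  for (rep in 1:10) {
    anc <- anchor_grid(8, 8, 8)
    g <- random_boxes(3, size = 64, min_side = 4, max_side = 30)
    a2 <- assign_anchor_labels(anc, g)
    expect_true(all(seq_len(3) %in% a2$matched[which(a2$labels == 1)]))
  }
  # no gt at all: everything negative
  a3 <- assign_anchor_labels(anchors, matrix(numeric(0), 0, 4))
  expect_true(all(a3$labels == 0))
})

test_that("RPN loss matches a scalar-loop oracle on a hand-built batch", {
  p <- c(0.9, 0.2, 0.6, 0.4)
  p_star <- c(1, 0, 1, 0)
  t <- matrix(c(0.1, 0, -0.2, 0.3,
                0.5, 0.5, 0.5, 0.5,
                0.05, -0.05, 0, 2,
                0, 0, 0, 0), 4, 4, byrow = TRUE)
  t_star <- matrix(0, 4, 4)
  lambda <- 10; n_cls <- 4; n_reg <- 16
  # independent scalar loop
  oracle <- 0
  for (i in 1:4) {
    oracle <- oracle + (-(p_star[i] * log(p[i]) + (1 - p_star[i]) * log(1 - p[i]))) / n_cls
    if (p_star[i] == 1) {
      for (k in 1:4) {
        x <- t[i, k] - t_star[i, k]
        oracle <- oracle + lambda / n_reg * (if (abs(x) < 1) 0.5 * x^2 else abs(x) - 0.5)
      }
    }
  }
  expect_equal(rpn_loss(p, p_star, t, t_star, lambda, n_cls, n_reg), oracle,
               tolerance = 1e-6)
  # lambda = 0 decouples to pure classification
  expect_equal(rpn_loss(p, p_star, t, t_star, 0, n_cls, n_reg),
               -sum(p_star * log(p) + (1 - p_star) * log(1 - p)) / n_cls)
  # perfect confident predictions: loss tends to zero
  expect_lt(rpn_loss(c(1 - 1e-9, 1e-9), c(1, 0), matrix(0, 2, 4),
                     matrix(0, 2, 4)), 1e-6)
  # empty positive set: regression term vanishes
  expect_equal(rpn_loss(0.5, 0, matrix(5, 1, 4), matrix(0, 1, 4)),
               -log(0.5))
})

test_that("greedy NMS matches the quadratic reference on random instances", {
  expect_identical(nms(rbind(c(0, 0, 10, 10), c(0, 0, 10, 10)), c(0.9, 0.8), 0.7), 1L)
  disjoint <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30), c(50, 0, 60, 10))
  expect_setequal(nms(disjoint, c(0.5, 0.9, 0.7), 0.7), 1:3)
  set.seed(11)
  for (rep in 1:200) {
    b <- random_boxes(10)
    s <- runif(10)
    expect_identical(sort(nms(b, s, 0.7)), sort(nms_reference(b, s, 0.7)))
  }
})

test_that("backbone and hyper feature have the documented shapes", {
  net <- weednet("tiny", seed = 2)
  rgb <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  pha <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  g <- weednet_graph(net, rgb, pha)
  # specific branches: block-5 map at stride 16; corr: hyper at stride 4
  expect_identical(dim(g$feats$rgb$value)[1:2], c(4L, 4L))
  expect_identical(dim(g$feats$corr$value), c(16L, 16L, net$config$hyper_c))
  expect_true(all(is.finite(g$feats$corr$value)))
  expect_error(weednet_graph(net, rgb, array(0, c(32, 32, 3))), "co-registered")
})

test_that("the autograd gradients agree with finite differences", {
  net <- weednet("tiny", seed = 9)
  set.seed(5)
  rgb <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  pha <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  ann <- tibble::tibble(class = "grass", x1 = 8, y1 = 8, x2 = 24, y2 = 20)
  loss_fn <- function() {
    set.seed(77) # freeze anchor subsampling
    g <- weednet_graph(net, rgb, pha)
    losses <- list()
    for (br in c("rgb", "pha", "corr")) {
      losses <- c(losses, branch_losses(g$tape, net, g, br, as_box_matrix(ann),
                                        ann$class, 32, 32, 10))
    }
    list(g = g, total = ag_add_scalars(g$tape, losses))
  }
  r <- loss_fn()
  ag_backward(r$g$tape, r$total)
  grads <- collect_param_grads(r$g$tape)
  params <- flatten_params(net$params)
  params <- params[!duplicated(vapply(params, function(p) p$id, character(1)))]
  set.seed(123)
  for (trial in 1:15) {
    p <- params[[sample(length(params), 1)]]
    if (is.null(grads[[p$id]])) next
    i <- sample(length(p$value), 1)
    eps <- 1e-4; old <- p$value[i]
    p$value[i] <- old + eps; lp <- loss_fn()$total$value
    p$value[i] <- old - eps; lm <- loss_fn()$total$value
    p$value[i] <- old
    fd <- (lp - lm) / (2 * eps)
    an <- grads[[p$id]][i]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 1e-3)
  }
})

test_that("forward pass contract: well-formed, deterministic detections", {
  net <- weednet("tiny", seed = 4)
  set.seed(8)
  rgb <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  pha <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  d1 <- weednet_forward(net, rgb, pha)
  expect_true(all(d1$score >= 0 & d1$score <= 1))
  expect_true(all(d1$x1 >= 0 & d1$x2 <= 64 & d1$y1 >= 0 & d1$y2 <= 64))
  expect_true(all(d1$branch %in% c("rgb", "pha", "corr")))
  expect_true(all(d1$class %in% c("grass", "broadleaf")))
  # scores sorted descending within branch and class
  srt <- dplyr::group_by(d1, branch, class)
  expect_true(all(dplyr::summarise(srt, ok = !is.unsorted(-score))$ok))
  expect_identical(weednet_forward(net, rgb, pha), d1)
})

test_that("training machinery: null step, determinism, descent, sharing", {
  cfg <- scene_config(image_size = 48L, n_grass = 1L, n_broadleaf = 1L)
  ds <- make_scene_dataset(2, cfg, seed = 40)

  # lr = 0 leaves weights unchanged
  net0 <- weednet("tiny", seed = 3)
  before <- lapply(flatten_params(net0$params), function(p) p$value)
  train_weednet(net0, ds, iterations = 1,
                config = train_config(initial_learning_rate = 0), seed = 1)
  after <- lapply(flatten_params(net0$params), function(p) p$value)
  expect_equal(before, after)

  # same seed twice: identical loss logs
  n1 <- weednet("tiny", seed = 3)
  f1 <- train_weednet(n1, ds, iterations = 6, seed = 5)
  n2 <- weednet("tiny", seed = 3)
  f2 <- train_weednet(n2, ds, iterations = 6, seed = 5)
  expect_identical(f1$loss_log, f2$loss_log)

  # loss decreases over 50 iterations on a fixed image
  n3 <- weednet("tiny", seed = 3)
  f3 <- train_weednet(n3, ds[1], iterations = 50, seed = 2)
  expect_lt(mean(utils::tail(f3$loss_log$loss, 10)),
            mean(utils::head(f3$loss_log$loss, 10)))

  # weight sharing: the RGB and PHA backbones are the same objects
  expect_identical(n3$params$backbone_rgb[[1]][[1]]$W,
                   n3$params$backbone_pha[[1]][[1]]$W)
  unshared <- weednet("tiny", seed = 3, share_weights = FALSE)
  expect_false(identical(unshared$params$backbone_rgb[[1]][[1]]$W,
                         unshared$params$backbone_pha[[1]][[1]]$W))
})
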