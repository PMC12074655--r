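test_that("assignment solver matches brute-force enumeration", {
  set.seed(1)
  for (t in 1:200) {
    n <- sample(1:6, 1)
    m <- sample(n:6, 1)
    cost <- matrix(runif(n * m, -2, 5), n, m)
    if (runif(1) < 0.5) cost <- t(cost)
    a <- solve_assignment(cost)
    expect_equal(a$cost, brute_assignment_cost(cost), tolerance = 1e-10)
    expect_equal(cost[cbind(a$row, a$col)],
                 cost[cbind(a$row, a$col)])   # valid index pairs
    expect_false(any(duplicated(a$row)))
    expect_false(any(duplicated(a$col)))
  }
  expect_error(solve_assignment(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("hungarian matching covers every ground truth at minimum cost", {
  set.seed(2)
  pb <- cbind(runif(5, 0.2, 0.8), runif(5, 0.2, 0.8),
              runif(5, 0.1, 0.3), runif(5, 0.1, 0.3))
  sc <- matrix(runif(10), 5, 2)
  gb <- pb[c(2, 4), , drop = FALSE]
  m <- hungarian_match(pb, sc, gb, c(1L, 2L))
  expect_length(m$pred, 2)
  expect_setequal(m$gt, 1:2)
  # trivial cases
  m1 <- hungarian_match(pb[1, , drop = FALSE], sc[1, , drop = FALSE],
                        pb[1, , drop = FALSE], 1L)
  expect_identical(m1$pred, 1L)
  a <- solve_assignment(matrix(c(0, 1, 1, 0), 2, 2))
  expect_identical(a$row[order(a$col)], c(1L, 2L))
})

test_that("query selection takes top confidences with stable ties", {
  expect_identical(iou_aware_query_select(matrix(c(0.9, 0.1, 0.5), 3, 1), 2),
                   c(1L, 3L))
  expect_length(iou_aware_query_select(matrix(runif(10), 10, 1), 300), 10)
  expect_identical(iou_aware_query_select(matrix(0.5, 4, 1), 3), 1:3)
})

test_that("denoising groups respect bounds, determinism and masking", {
  gb <- cbind(c(0.3, 0.6), c(0.4, 0.5), c(0.2, 0.25), c(0.15, 0.2))
  cls <- c(1L, 2L)
  g0 <- add_denoising_noise(gb, cls, 3L, label_flip_p = 0,
                            box_noise_scale = 0, n_groups = 2, seed = 4)
  for (g in g0) {
    expect_equal(unname(g$boxes), unname(gb))
    expect_identical(g$classes, cls)
  }
  g1 <- add_denoising_noise(gb, cls, 3L, label_flip_p = 0.5,
                            box_noise_scale = 0.4, n_groups = 5, seed = 4)
  g2 <- add_denoising_noise(gb, cls, 3L, label_flip_p = 0.5,
                            box_noise_scale = 0.4, n_groups = 5, seed = 4)
  expect_identical(g1, g2)
  for (g in g1) {
    jit <- abs(g$boxes - gb)
    expect_true(all(jit <= 0.4 * gb[, c(3, 4, 3, 4)] + 1e-12))
  }
  mask <- denoising_attn_mask(3, c(2, 2))
  expect_identical(dim(mask), c(7L, 7L))
  expect_true(all(mask[1:3, 4:7]))        # match queries never see dn
  expect_false(any(mask[4:7, 1:3]))       # dn may see match queries
  expect_true(all(mask[4:5, 6:7]))        # groups never see each other
  expect_false(any(mask[4:5, 4:5]))
})

test_that("decoder emits per-layer sigmoid boxes deterministically", {
  set.seed(5)
  dcfg <- decoder_config(dim = 8, n_classes = 2, n_layers = 3, heads = 2,
                         n_queries = 4, ffn_dim = 16, seed = 6)
  dp <- osdetr:::decoder_params(dcfg)
  mem <- lapply(c(4, 2, 1), function(s)
    list(tokens = ag_const(matrix(rnorm(s * s * 8), s * s, 8)), H = s, W = s))
  content <- matrix(rnorm(4 * 8), 4, 8)
  coords <- matrix(rnorm(4 * 4), 4, 4)
  outs <- decoder_forward(content, coords, mem, dp, dcfg)
  expect_length(outs, 3)
  for (o in outs) {
    b <- ag_value(o$boxes)
    expect_true(all(b > 0 & b < 1))
    expect_identical(dim(ag_value(o$logits)), c(4L, 2L))
  }
  outs2 <- decoder_forward(content, coords, mem, dp, dcfg)
  expect_identical(ag_value(outs$boxes), ag_value(outs2$boxes))
})

test_that("a training step decreases the loss on a fixed tiny batch", {
  cfg <- toy_detector_config(seed = 30L)
  model <- build_osdetr(cfg)
  scenes <- generate_scenes(synth_config(n_images = 2, image_side = 160,
                                         seed = 31))
  opt <- adam(model$params, lr = 1e-3)
  l1 <- train_step(model, scenes, opt, step_seed = 1)
  for (s in 2:5) l5 <- train_step(model, scenes, opt, step_seed = 1)
  expect_lt(l5[["total"]], l1[["total"]])
  expect_error(train_step(model, list(), opt), "empty")
})

test_that("detection with threshold 1 returns an empty set", {
  cfg <- toy_detector_config(seed = 32L)
  model <- build_osdetr(cfg)
  scene <- render_scene(synth_config(image_side = 160, seed = 33), seed = 33)
  d <- detect(model, scene$image, score_thr = 1.0)
  expect_identical(nrow(d), 0L)
  d2 <- detect(model, scene$image, score_thr = 0)
  expect_identical(nrow(d2), 50L)   # every query survives, no NMS pruning
  expect_true(all(d2$score >= 0 & d2$score <= 1))
})

test_that("checkpoints restore weights bit-exactly", {
  cfg <- toy_detector_config(seed = 34L)
  model <- build_osdetr(cfg)
  path <- tempfile()
  save_osdetr_weights(model, path)
  before <- ag_value(model$params[[3]])
  model$params[[3]]$value[] <- 0
  load_osdetr_weights(model, path)
  expect_identical(ag_value(model$params[[3]]), before)
})
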