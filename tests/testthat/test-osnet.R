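test_that("orthogonal projection matches analytic and loop oracles", {
  bank <- build_filter_bank(4, 3, "special_orthogonal", seed = 1)
  # channel equal to its own filter: projection = Frobenius norm^2 = n
  x <- array(0, c(2, 4, 3, 3))
  for (i in 1:4) { x[1, i, , ] <- bank$matrices[i, , ]
                   x[2, i, , ] <- bank$matrices[i, , ] }
  f <- ag_value(orthogonal_projection(x, bank))
  expect_equal(f, matrix(3, 2, 4), tolerance = 1e-12)
  expect_equal(ag_value(orthogonal_projection(array(0, c(1, 4, 3, 3)), bank)),
               matrix(0, 1, 4))

  set.seed(2)
  bank2 <- build_filter_bank(2, 3, "special_orthogonal", seed = 3)
  xr <- array(rnorm(2 * 2 * 3 * 3), c(2, 2, 3, 3))
  f2 <- ag_value(orthogonal_projection(xr, bank2))
  for (b in 1:2) for (i in 1:2) {
    acc <- 0
    for (u in 1:3) for (v in 1:3)
      acc <- acc + xr[b, i, u, v] * bank2$matrices[i, u, v]
    expect_lt(abs(f2[b, i] - acc), 1e-6)
  }
})

test_that("orthogonal projection is linear in the feature map", {
  set.seed(4)
  bank <- build_filter_bank(3, 4, "special_orthogonal", seed = 5)
  F1 <- array(rnorm(36), c(1, 3, 4, 4)); F2 <- array(rnorm(36), c(1, 3, 4, 4))
  lhs <- ag_value(orthogonal_projection(2.5 * F1 - 1.2 * F2, bank))
  rhs <- 2.5 * ag_value(orthogonal_projection(F1, bank)) -
    1.2 * ag_value(orthogonal_projection(F2, bank))
  expect_lt(max(abs(lhs - rhs)), 1e-5)
})

test_that("attention weights are sigmoid-bounded and match a dense oracle", {
  set.seed(6)
  mlp <- attention_mlp_params(8, reduction = 4)
  f <- matrix(rnorm(16), 2, 8)
  a <- ag_value(attention_weights(f, mlp))
  expect_true(all(a > 0 & a < 1))
  # zero input and zero biases -> exactly 0.5
  mlp0 <- attention_mlp_params(8, reduction = 4)
  mlp0$fc2$b$value[] <- 0
  expect_equal(ag_value(attention_weights(matrix(0, 1, 8), mlp0)),
               matrix(0.5, 1, 8))
  h <- pmax(f %*% ag_value(mlp$fc1$W) +
              rep(ag_value(mlp$fc1$b), each = 2), 0)
  z <- h %*% ag_value(mlp$fc2$W) + rep(ag_value(mlp$fc2$b), each = 2)
  expect_lt(max(abs(a - 1 / (1 + exp(-z)))), 1e-6)
})

test_that("channel shuffle is the reshape-transpose permutation", {
  expect_identical(channel_shuffle_perm(4, 1), 1:4)
  expect_identical(channel_shuffle_perm(4, 2), c(1L, 3L, 2L, 4L))
  expect_error(channel_shuffle_perm(5, 2), "divisible")
  set.seed(7)
  x <- array(rnorm(2 * 6 * 2 * 2), c(2, 6, 2, 2))
  y <- channel_shuffle(x, 3)
  expect_equal(sort(as.numeric(y)), sort(as.numeric(x)))
  # composing with the inverse permutation restores the input
  for (cfg in list(c(8, 2), c(12, 3), c(64, 8))) {
    perm <- channel_shuffle_perm(cfg[1], cfg[2])
    expect_identical(order(perm)[perm], seq_len(cfg[1]))
  }
  # shuffle is sign-preserving: relu(shuffle(relu(x))) == shuffle(relu(x))
  xr <- channel_shuffle(pmax(x, 0), 2)
  expect_identical(pmax(xr, 0), xr)
})

test_that("osnet block obeys shape/positivity and composes from its parts", {
  cfg <- osnet_block_config(8, 16, stride = 2, shuffle_groups = 2,
                            attention_reduction = 4, seed = 8)
  params <- osnet_block_params(cfg)
  bank <- build_filter_bank(16, 8, "special_orthogonal", seed = 9)
  set.seed(9)
  x <- array(rnorm(2 * 8 * 16 * 16), c(2, 8, 16, 16))
  y <- ag_value(osnet_block_forward(x, cfg, bank, params))
  expect_identical(dim(y), c(2L, 16L, 8L, 8L))
  expect_true(all(y >= 0))

  # with attention forced to 1 and groups 1, the block is a plain residual
  # block; rebuild it from the independently tested sub-operations
  cfg1 <- osnet_block_config(8, 8, stride = 1, shuffle_groups = 1,
                             attention_reduction = 4, use_norm = FALSE,
                             seed = 10)
  p1 <- osnet_block_params(cfg1)
  xs <- array(rnorm(1 * 8 * 6 * 6), c(1, 8, 6, 6))
  bank1 <- build_filter_bank(8, 6, "special_orthogonal", seed = 2)
  ones <- matrix(1, 1, 8)
  got <- ag_value(osnet_block_forward(xs, cfg1, bank1, p1,
                                      alpha_override = ones))
  h <- pmax(naive_conv2d(xs, ag_value(p1$conv1$W), ag_value(p1$conv1$b)), 0)
  Fm <- naive_conv2d(h, ag_value(p1$conv2$W), ag_value(p1$conv2$b))
  expect_lt(max(abs(got - pmax(Fm + xs, 0))), 1e-6)
})

test_that("backbone emits S3/S4/S5 at strides 8/16/32, reproducibly", {
  cfg <- backbone_config(input_channels = 1, stem_channels = 4,
                         stage_channels = c(4, 8, 8),
                         stage_depths = c(1, 1, 1),
                         attention_reduction = 2, seed = 3)
  bb <- build_backbone(cfg)
  x <- array(stats::rnorm(160 * 160), c(1, 1, 160, 160))
  fs <- backbone_forward(bb, x, training = FALSE)
  expect_identical(vapply(fs, function(f) dim(ag_value(f))[3], 1), 
                   c(S3 = 20, S4 = 10, S5 = 5))
  bb2 <- build_backbone(cfg)
  fs2 <- backbone_forward(bb2, x, training = FALSE)
  expect_identical(ag_value(fs$S5), ag_value(fs2$S5))
  expect_error(backbone_forward(bb, array(0, c(1, 1, 100, 100))),
               "divisible")
})
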