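test_that("token flattening round-trips a feature map", {
  set.seed(1)
  x <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  t1 <- fmap_tokens(ag_const(x), 2)
  back <- ag_value(tokens_fmap(t1, 4, 4))
  expect_equal(back[1, , , ], x[2, , , ])
})

test_that("repblock branches behave and reparameterize exactly", {
  set.seed(2)
  # zero conv weights, no identity (cin != cout): zero pre-activation
  p0 <- repblock_params(3, 5, seed = 3)
  p0$conv3$W$value[] <- 0; p0$conv3$b$value[] <- 0
  p0$conv1$W$value[] <- 0; p0$conv1$b$value[] <- 0
  x <- array(rnorm(1 * 3 * 6 * 6), c(1, 3, 6, 6))
  expect_equal(ag_value(repblock_forward(x, p0, "train")),
               array(0, c(1, 5, 6, 6)))
  # identity branch only: pre-activation output equals input
  pi_ <- repblock_params(4, 4, seed = 4)
  pi_$conv3$W$value[] <- 0; pi_$conv3$b$value[] <- 0
  pi_$conv1$W$value[] <- 0; pi_$conv1$b$value[] <- 0
  xi <- array(abs(rnorm(1 * 4 * 5 * 5)), c(1, 4, 5, 5))
  expect_equal(ag_value(repblock_forward(xi, pi_, "train")), xi)

  # train vs merged deploy agree on 100 random inputs
  p <- repblock_params(4, 4, seed = 5)
  pm <- reparameterize(p)
  worst <- 0
  for (i in 1:100) {
    xr <- array(rnorm(4 * 5 * 5), c(1, 4, 5, 5))
    a <- ag_value(repblock_forward(xr, p, "train"))
    b <- ag_value(repblock_forward(xr, pm, "deploy"))
    worst <- max(worst, max(abs(a - b)))
  }
  expect_lt(worst, 1e-5)
  expect_error(repblock_forward(x, list(identity = TRUE), "deploy"), "merged")
})

test_that("aifi preserves shape and never touches S3/S4", {
  set.seed(6)
  dim_ <- 8
  dc <- deform_config(dim_, heads = 2, r = 1, s = 0.2, bias_enabled = FALSE)
  ap <- aifi_params(dim_, dc, ffn_dim = 16, seed = 7)
  S5 <- array(rnorm(2 * dim_ * 4 * 4), c(2, dim_, 4, 4))
  out <- ag_value(aifi(S5, ap, dc))
  expect_identical(dim(out), dim(S5))
  expect_identical(out, ag_value(aifi(S5, ap, dc)))  # no hidden state
})

test_that("aifi composes flatten, attention, FFN and layer norms", {
  set.seed(8)
  dim_ <- 4
  dc <- deform_config(dim_, heads = 2, r = 1, s = 0.2, bias_enabled = FALSE)
  ap <- aifi_params(dim_, dc, ffn_dim = 8, seed = 9)
  S5 <- array(rnorm(dim_ * 9), c(1, dim_, 3, 3))
  got <- ag_value(aifi(S5, ap, dc))
  X <- ag_value(fmap_tokens(ag_const(S5), 1))
  att <- reference_attention(X, ap$dat, 2)
  lnorm <- function(M, p) {
    mu <- rowMeans(M); xc <- M - mu
    sd_ <- sqrt(rowMeans(xc^2) + 1e-5)
    sweep(sweep(xc / sd_, 2, ag_value(p$gamma), "*"), 2, ag_value(p$beta), "+")
  }
  t1 <- lnorm(X + att, ap$ln1)
  ff <- pmax(sweep(t1 %*% ag_value(ap$ffn1$W), 2, ag_value(ap$ffn1$b), "+"),
             0) %*% ag_value(ap$ffn2$W)
  ff <- sweep(ff, 2, ag_value(ap$ffn2$b), "+")
  t2 <- lnorm(t1 + ff, ap$ln2)
  ref <- ag_value(tokens_fmap(ag_const(t2), 3, 3))
  expect_lt(max(abs(got - ref)), 1e-5)
})

test_that("ccfm preserves per-scale spatial sides and maps zero to zero", {
  set.seed(10)
  hd <- 8
  enc <- build_encoder(c(hd, hd, hd),
                       encoder_config(hidden_dim = hd, heads = 2, r = 1,
                                      bias_enabled = FALSE, ffn_dim = 16,
                                      n_repblocks = 2, seed = 11))
  S3 <- array(rnorm(hd * 16 * 16), c(1, hd, 16, 16))
  S4 <- array(rnorm(hd * 8 * 8), c(1, hd, 8, 8))
  S5 <- array(rnorm(hd * 4 * 4), c(1, hd, 4, 4))
  out <- ccfm(S3, S4, S5, enc$params)
  expect_identical(vapply(out, function(o) dim(ag_value(o))[3], 1),
                   c(S3 = 16, S4 = 8, S5 = 4))
  z <- lapply(list(16, 8, 4), function(s) array(0, c(1, hd, s, s)))
  outz <- ccfm(z[[1]], z[[2]], z[[3]], enc$params)
  for (o in outz) expect_equal(max(abs(ag_value(o))), 0)
})

test_that("a fusion unit equals its hand-composed parts", {
  set.seed(12)
  hd <- 4
  enc <- build_encoder(c(hd, hd, hd),
                       encoder_config(hidden_dim = hd, heads = 2, r = 1,
                                      bias_enabled = FALSE, ffn_dim = 8,
                                      n_repblocks = 2, seed = 13))
  fp <- enc$params$td4
  up <- array(rnorm(hd * 4 * 4), c(1, hd, 4, 4))
  lat <- array(rnorm(hd * 8 * 8), c(1, hd, 8, 8))
  got <- ag_value(osdetr:::fusion_forward(ag_upsample2(ag_const(up)),
                                          ag_const(lat), fp))
  # oracle: nearest-neighbour upsample + concat + 1x1 conv + RepBlocks via
  # the naive dense convolution
  up2 <- array(0, c(1, hd, 8, 8))
  for (y in 1:8) for (x in 1:8) up2[1, , y, x] <- up[1, , ceiling(y / 2),
                                                     ceiling(x / 2)]
  cat2 <- array(0, c(1, 2 * hd, 8, 8))
  cat2[1, 1:hd, , ] <- up2[1, , , ]; cat2[1, (hd + 1):(2 * hd), , ] <- lat[1, , , ]
  h <- pmax(naive_conv2d(cat2, ag_value(fp$reduce$W), ag_value(fp$reduce$b),
                         stride = 1, pad = 0), 0)
  for (rp in fp$reps) {
    y3 <- naive_conv2d(h, ag_value(rp$conv3$W), ag_value(rp$conv3$b))
    y1 <- naive_conv2d(h, ag_value(rp$conv1$W), ag_value(rp$conv1$b), pad = 0)
    h <- pmax(y3 + y1 + h, 0)
  }
  expect_lt(max(abs(got - h)), 1e-5)
})

test_that("encoder output has three scales at the hidden width", {
  set.seed(14)
  enc <- build_encoder(c(3, 5, 7),
                       encoder_config(hidden_dim = 8, heads = 2, r = 1,
                                      bias_enabled = FALSE, ffn_dim = 16,
                                      n_repblocks = 2, seed = 15))
  feats <- list(S3 = array(rnorm(3 * 16 * 16), c(1, 3, 16, 16)),
                S4 = array(rnorm(5 * 8 * 8), c(1, 5, 8, 8)),
                S5 = array(rnorm(7 * 4 * 4), c(1, 7, 4, 4)))
  out <- encoder_forward(enc, feats)
  expect_length(out, 3)
  for (o in out) expect_identical(dim(ag_value(o))[2], 8L)
  # aifi path only sees S5: perturbing S3/S4 leaves the attended S5 alone
  feats2 <- feats
  feats2$S3 <- feats2$S3 + 1; feats2$S4 <- feats2$S4 - 1
  p5a <- ag_value(aifi(ag_conv2d(feats$S5, enc$params$proj[[3]]$W,
                                 enc$params$proj[[3]]$b, 1, 0),
                       enc$params$aifi, enc$cfg$dat))
  p5b <- ag_value(aifi(ag_conv2d(feats2$S5, enc$params$proj[[3]]$W,
                                 enc$params$proj[[3]]$b, 1, 0),
                       enc$params$aifi, enc$cfg$dat))
  expect_identical(p5a, p5b)
})
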