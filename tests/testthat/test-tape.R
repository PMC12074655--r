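test_that("core tape operations match finite differences", {
  set.seed(1)
  W <- ag_param(matrix(rnorm(12), 3, 4))
  b <- ag_param(rnorm(4))
  x <- matrix(rnorm(15), 5, 3)
  M <- matrix(rnorm(20), 5, 4)
  f <- function() ag_mean(ag_mul(ag_softmax(ag_relu(ag_linear(x, W, b))), M))
  loss <- f(); ag_zero_grad(list(W, b)); ag_backward(loss)
  expect_lt(max(abs(fd_grad(f, W) - as.numeric(W$grad))), 1e-6)
  expect_lt(max(abs(fd_grad(f, b) - as.numeric(b$grad))), 1e-6)
})

test_that("convolution matches the naive dense oracle, values and gradients", {
  set.seed(2)
  x <- array(rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  W <- ag_param(array(rnorm(4 * 3 * 3 * 3, sd = 0.3), c(4, 3, 3, 3)))
  b <- ag_param(rnorm(4))
  for (stride in c(1, 2)) {
    got <- ag_value(ag_conv2d(x, W, b, stride = stride, pad = 1))
    ref <- naive_conv2d(x, ag_value(W), ag_value(b), stride = stride, pad = 1)
    expect_lt(max(abs(got - ref)), 1e-10)
  }
  M <- array(rnorm(2 * 4 * 3 * 3), c(2, 4, 3, 3))
  f <- function() ag_mean(ag_mul(ag_conv2d(x, W, b, stride = 2, pad = 1), M))
  loss <- f(); ag_zero_grad(list(W, b)); ag_backward(loss)
  idx <- sample(length(ag_value(W)), 8)
  expect_lt(max(abs(fd_grad(f, W, idx) - as.numeric(W$grad)[idx])), 1e-6)
})

test_that("batch and layer normalization gradients are exact", {
  set.seed(3)
  bnp <- bn_param(3)
  x <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  M <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  f <- function() ag_mean(ag_mul(ag_batchnorm(x, bnp$gamma, bnp$beta,
                                              bnp$state, TRUE), M))
  loss <- f(); ag_zero_grad(list(bnp$gamma, bnp$beta)); ag_backward(loss)
  expect_lt(max(abs(fd_grad(f, bnp$gamma) - as.numeric(bnp$gamma$grad))), 1e-6)
  lnp <- ln_param(4)
  xm <- matrix(rnorm(20), 5, 4); Mm <- matrix(rnorm(20), 5, 4)
  f2 <- function() ag_mean(ag_mul(ag_layernorm(xm, lnp$gamma, lnp$beta), Mm))
  loss <- f2(); ag_zero_grad(list(lnp$gamma, lnp$beta)); ag_backward(loss)
  expect_lt(max(abs(fd_grad(f2, lnp$beta) - as.numeric(lnp$beta$grad))), 1e-6)
})

test_that("fused multi-head attention equals its composed reference", {
  set.seed(4)
  n <- 6; dim_ <- 8; heads <- 2
  q <- ag_param(matrix(rnorm(n * dim_), n, dim_))
  k <- ag_param(matrix(rnorm(n * dim_), n, dim_))
  v <- ag_param(matrix(rnorm(n * dim_), n, dim_))
  out <- ag_value(ag_mha_fused(q, k, v, heads))
  dh <- dim_ / heads
  ref <- matrix(0, n, dim_)
  for (m in 1:heads) {
    idx <- ((m - 1) * dh + 1):(m * dh)
    s <- ag_value(q)[, idx] %*% t(ag_value(k)[, idx]) / sqrt(dh)
    A <- exp(s - apply(s, 1, max)); A <- A / rowSums(A)
    ref[, idx] <- A %*% ag_value(v)[, idx]
  }
  expect_lt(max(abs(out - ref)), 1e-12)
  M <- matrix(rnorm(n * dim_), n, dim_)
  bias <- list(ag_param(matrix(rnorm(n * n, sd = 0.1), n, n)),
               ag_param(matrix(rnorm(n * n, sd = 0.1), n, n)))
  f <- function() ag_mean(ag_mul(ag_mha_fused(q, k, v, heads,
                                              biases = bias), M))
  loss <- f(); ag_zero_grad(c(list(q, k, v), bias)); ag_backward(loss)
  for (p in c(list(q, k, v), bias)) {
    idx <- sample(length(p$value), 5)
    expect_lt(max(abs(fd_grad(f, p, idx) - as.numeric(p$grad)[idx])), 1e-5)
  }
})

test_that("softmax rows sum to one and attention masks block fully", {
  set.seed(5)
  s <- ag_softmax(matrix(rnorm(12), 3, 4))
  expect_equal(rowSums(ag_value(s)), rep(1, 3))
  q <- matrix(rnorm(8), 2, 4); k <- matrix(rnorm(12), 3, 4)
  v <- matrix(rnorm(12), 3, 4)
  mask <- matrix(c(0, -1e9, 0, 0, 0, -1e9), 2, 3)
  out <- ag_value(ag_mha_fused(q, k, v, 1, mask = mask))
  # blocked keys contribute nothing: recompute without them
  A <- exp((q %*% t(k)) / 2 + mask)
  A <- A / rowSums(A)
  expect_lt(max(abs(out - A %*% v)), 1e-10)
  expect_lt(A[2, 1], 1e-12)   # the masked query/key pair carries no weight
})

test_that("adam drives a quadratic toward its minimum", {
  p <- ag_param(c(5, -3))
  opt <- adam(list(p), lr = 0.1)
  for (i in 1:200) {
    loss <- ag_sum(ag_mul(ag_sub(p, c(1, 2)), ag_sub(p, c(1, 2))))
    ag_zero_grad(list(p)); ag_backward(loss); adam_step(opt)
  }
  expect_lt(max(abs(ag_value(p) - c(1, 2))), 1e-3)
})
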