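test_that("scale_box reproduces the defining corner arithmetic", {
  b <- data.frame(cx = 50, cy = 50, w = 20, h = 20)
  expect_equal(as.numeric(scale_box(b, 1)), c(40, 40, 60, 60))
  expect_equal(as.numeric(scale_box(b, 0.7)), c(43, 43, 57, 57))
  b2 <- data.frame(cx = 55, cy = 55, w = 20, h = 20)
  expect_equal(as.numeric(scale_box(b2, 0.7)), c(48, 48, 62, 62))
  expect_error(scale_box(b, 0), "positive")
})

test_that("inner IoU handles identity, disjoint and the worked example", {
  a <- data.frame(cx = 50, cy = 50, w = 20, h = 20)
  expect_equal(inner_iou(a, a, 0.7), 1)
  far <- data.frame(cx = 150, cy = 50, w = 10, h = 10)
  expect_equal(inner_iou(data.frame(cx = 50, cy = 50, w = 10, h = 10),
                         far, 0.7), 0)
  b <- data.frame(cx = 55, cy = 55, w = 20, h = 20)
  expect_equal(inner_iou(a, b, 0.7), 81 / 311, tolerance = 1e-12)
})

test_that("inner IoU is symmetric and scale invariant", {
  set.seed(1)
  for (i in 1:50) {
    a <- data.frame(cx = runif(1, 20, 80), cy = runif(1, 20, 80),
                    w = runif(1, 5, 40), h = runif(1, 5, 40))
    b <- data.frame(cx = runif(1, 20, 80), cy = runif(1, 20, 80),
                    w = runif(1, 5, 40), h = runif(1, 5, 40))
    expect_identical(inner_iou(a, b, 0.7), inner_iou(b, a, 0.7))
    lam <- runif(1, 0.5, 3)
    expect_equal(inner_iou(a * lam, b * lam, 0.7), inner_iou(a, b, 0.7),
                 tolerance = 1e-9)
  }
})

test_that("corner penalties normalize squared distances by the image diagonal", {
  gt_c <- data.frame(bl = 43, bt = 43, br = 57, bb = 57)
  an_c <- data.frame(bl = 48, bt = 48, br = 62, bb = 62)
  p <- corner_penalty(gt_c, an_c, 100, 100)
  expect_equal(as.numeric(p), c(0.0025, 0.0025))
  expect_equal(as.numeric(corner_penalty(gt_c, gt_c, 100, 100)), c(0, 0))
  opp <- corner_penalty(data.frame(bl = 0, bt = 0, br = 0, bb = 0),
                        data.frame(bl = 100, bt = 100, br = 100, bb = 100),
                        100, 100)
  expect_equal(as.numeric(opp), c(1, 1))
})

test_that("IACD-IoU combines inner IoU and penalties as defined", {
  a <- data.frame(cx = 50, cy = 50, w = 20, h = 20)
  b <- data.frame(cx = 55, cy = 55, w = 20, h = 20)
  expect_equal(iacd_iou(a, a, 0.7, 100, 100), 1)
  expect_equal(iacd_iou(a, b, 0.7, 100, 100), 81 / 311 - 0.005,
               tolerance = 1e-12)
  far <- data.frame(cx = 90, cy = 90, w = 10, h = 10)
  near0 <- data.frame(cx = 10, cy = 10, w = 10, h = 10)
  expect_lt(iacd_iou(near0, far, 0.7, 100, 100), 0)
})

test_that("IACD-IoU equals 1 exactly when boxes coincide, and only then", {
  set.seed(2)
  for (i in 1:100) {
    a <- data.frame(cx = runif(1, 20, 80), cy = runif(1, 20, 80),
                    w = runif(1, 5, 30), h = runif(1, 5, 30))
    expect_equal(iacd_iou(a, a, 0.7, 100, 100), 1)
    b <- a + c(runif(1, 0.1, 5), 0, 0, 0)
    expect_lt(iacd_iou(a, b, 0.7, 100, 100), 1)
  }
})

test_that("for equal-size boxes the penalty is independent of the ratio", {
  set.seed(3)
  for (i in 1:20) {
    w <- runif(1, 5, 30); h <- runif(1, 5, 30)
    a <- data.frame(cx = runif(1, 30, 70), cy = runif(1, 30, 70), w = w, h = h)
    b <- data.frame(cx = runif(1, 30, 70), cy = runif(1, 30, 70), w = w, h = h)
    p1 <- corner_penalty(scale_box(a, 0.7), scale_box(b, 0.7), 100, 100)
    p2 <- corner_penalty(scale_box(a, 1), scale_box(b, 1), 100, 100)
    expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-9)
  }
})

test_that("rasterized oracle matches analytic IoU and the literal scan", {
  u1 <- list(bl = 0, bt = 0, br = 1, bb = 1)
  expect_equal(rasterized_iou_oracle(u1, u1, 0.01), 1)
  half <- list(bl = 0.5, bt = 0, br = 1.5, bb = 1)
  expect_lt(abs(rasterized_iou_oracle(u1, half, 0.01) - 1 / 3), 2 * 0.01)
  # factorized lattice counting equals the literal cell-by-cell scan
  set.seed(4)
  for (i in 1:10) {
    a <- list(bl = runif(1, 0, 2), bt = runif(1, 0, 2))
    a$br <- a$bl + runif(1, 0.5, 2); a$bb <- a$bt + runif(1, 0.5, 2)
    b <- list(bl = runif(1, 0, 2), bt = runif(1, 0, 2))
    b$br <- b$bl + runif(1, 0.5, 2); b$bb <- b$bt + runif(1, 0.5, 2)
    expect_equal(rasterized_iou_oracle(a, b, 0.1),
                 naive_raster_iou(a, b, 0.1), tolerance = 1e-12)
  }
  # step-convergence toward the closed form
  for (i in 1:20) {
    a <- list(bl = runif(1, 0, 5), bt = runif(1, 0, 5))
    a$br <- a$bl + runif(1, 2, 6); a$bb <- a$bt + runif(1, 2, 6)
    b <- list(bl = a$bl + runif(1, -2, 2), bt = a$bt + runif(1, -2, 2))
    b$br <- b$bl + runif(1, 2, 6); b$bb <- b$bt + runif(1, 2, 6)
    closed <- iou_corners(as.data.frame(a), as.data.frame(b))
    for (st in c(0.1, 0.01))
      expect_lt(abs(rasterized_iou_oracle(a, b, st) - closed), 5 * st)
  }
})

test_that("IACD loss is zero at identity and decreases toward the target", {
  g <- data.frame(cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  expect_equal(iacd_loss(g, g), 0)
  # translation sweep: loss non-increasing as the anchor approaches the gt
  shifts <- seq(0.3, 0, length.out = 50)
  losses <- vapply(shifts, function(s)
    iacd_loss(data.frame(cx = 0.5 + s, cy = 0.5, w = 0.2, h = 0.2), g), 1.0)
  expect_true(all(diff(losses) <= 1e-12))
  expect_error(iacd_loss(rbind(g, g), g), "equal row counts")
})

test_that("tape IACD loss matches the numeric loss and finite differences", {
  set.seed(5)
  for (mode in c("scaled", "original")) {
    G <- cbind(runif(4, 0.3, 0.7), runif(4, 0.3, 0.7),
               runif(4, 0.1, 0.3), runif(4, 0.1, 0.3))
    P0 <- G + 0.03   # offset, well away from any subgradient kink
    p <- ag_param(P0)
    f <- function() ag_iacd_loss(p, G, ratio = 0.7, corner_mode = mode)
    expect_equal(ag_value(f()),
                 iacd_loss(as.data.frame(`colnames<-`(P0, c("cx","cy","w","h"))),
                           as.data.frame(`colnames<-`(G, c("cx","cy","w","h"))),
                           corner_mode = mode),
                 tolerance = 1e-12)
    loss <- f()
    ag_zero_grad(list(p))
    ag_backward(loss)
    expect_lt(max(abs(fd_grad(f, p, eps = 1e-6) - as.numeric(p$grad))), 1e-4)
  }
})

test_that("corner-mode flag switches the penalty corners", {
  a <- data.frame(cx = 50, cy = 50, w = 20, h = 10)
  b <- data.frame(cx = 60, cy = 50, w = 30, h = 10)   # different sizes
  sc <- iacd_iou(a, b, 0.7, 100, 100, corner_mode = "scaled")
  or <- iacd_iou(a, b, 0.7, 100, 100, corner_mode = "original")
  expect_false(isTRUE(all.equal(sc, or)))
})
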