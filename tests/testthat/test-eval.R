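test_that("precision and recall follow the confusion-count definitions", {
  expect_equal(precision_recall(9, 1, 1), c(precision = 0.9, recall = 0.9))
  expect_equal(precision_recall(0, 0, 0), c(precision = 0, recall = 0))
  expect_equal(precision_recall(5, 0, 5), c(precision = 1, recall = 0.5))
})

test_that("single-detection AP depends on the IoU threshold", {
  gts <- data.frame(image_id = 1, class_id = 1, cx = 50, cy = 50,
                    w = 20, h = 20)
  det_good <- data.frame(image_id = 1, class_id = 1, cx = 50.5, cy = 50,
                         w = 20, h = 20, score = 0.7)
  iou <- iou_cxcywh(det_good[, 3:6], gts[, 3:6])
  expect_gt(iou, 0.9)
  expect_equal(average_precision(det_good, gts, 0.5), 1)
  # IoU about 0.6: TP at 0.5, no TP at 0.75
  det_ok <- data.frame(image_id = 1, class_id = 1, cx = 55, cy = 50,
                       w = 20, h = 20, score = 0.7)
  expect_gt(iou_cxcywh(det_ok[, 3:6], gts[, 3:6]), 0.5)
  expect_lt(iou_cxcywh(det_ok[, 3:6], gts[, 3:6]), 0.75)
  expect_equal(average_precision(det_ok, gts, 0.75), 0)
})

test_that("AP agrees with the exhaustive threshold-sweep oracle", {
  set.seed(1)
  for (t in 1:5) {
    n_gt <- sample(3:6, 1)
    gts <- data.frame(image_id = sample(1:2, n_gt, replace = TRUE),
                      class_id = 1,
                      cx = runif(n_gt, 30, 70), cy = runif(n_gt, 30, 70),
                      w = runif(n_gt, 10, 25), h = runif(n_gt, 10, 25))
    # 20 detections: some near gts, some junk
    rows <- lapply(1:20, function(i) {
      if (i <= n_gt) {
        g <- gts[i, ]
        data.frame(image_id = g$image_id, class_id = 1,
                   cx = g$cx + rnorm(1, 0, 4), cy = g$cy + rnorm(1, 0, 4),
                   w = g$w * runif(1, 0.8, 1.2), h = g$h * runif(1, 0.8, 1.2),
                   score = runif(1))
      } else {
        data.frame(image_id = sample(1:2, 1), class_id = 1,
                   cx = runif(1, 0, 100), cy = runif(1, 0, 100),
                   w = runif(1, 5, 20), h = runif(1, 5, 20),
                   score = runif(1))
      }
    })
    dets <- do.call(rbind, rows)
    expect_equal(average_precision(dets, gts, 0.5), sweep_ap(dets, gts, 0.5),
                 tolerance = 1e-6)
  }
})

test_that("AP is invariant to monotone score rescaling", {
  set.seed(2)
  gts <- data.frame(image_id = 1, class_id = 1, cx = c(30, 70),
                    cy = c(30, 70), w = c(20, 15), h = c(20, 15))
  dets <- data.frame(image_id = 1, class_id = 1,
                     cx = c(31, 69, 50), cy = c(30, 71, 50),
                     w = c(20, 15, 10), h = c(19, 15, 10),
                     score = c(0.9, 0.4, 0.6))
  ap1 <- average_precision(dets, gts, 0.5)
  dets2 <- dets; dets2$score <- plogis(5 * dets$score - 2)   # monotone map
  expect_equal(average_precision(dets2, gts, 0.5), ap1)
})

test_that("mAP range behaves across thresholds", {
  gts <- data.frame(image_id = 1, class_id = 1, cx = 50, cy = 50,
                    w = 20, h = 20)
  perfect <- data.frame(image_id = 1, class_id = 1, cx = 50, cy = 50,
                        w = 20, h = 20, score = 0.9)
  expect_equal(unname(map_range(perfect, gts)), c(1, 1))
  # detection with IoU just above 0.5: only the first threshold passes
  det <- data.frame(image_id = 1, class_id = 1, cx = 50, cy = 50,
                    w = 20, h = 20, score = 0.9)
  det$cx <- 50 + 20 * (1 - 0.52 * 2 / (1 + 0.52))  # IoU ~ 0.52
  iou <- iou_cxcywh(det[, 3:6], gts[, 3:6])
  expect_true(iou > 0.5 && iou < 0.55)
  m <- map_range(det, gts)
  expect_equal(unname(m), c(1, 0.1))
  empty <- data.frame(image_id = integer(), class_id = integer(),
                      cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), score = numeric())
  expect_equal(unname(map_range(empty, gts)), c(0, 0))
  # the averaged range can never exceed mAP@50
  set.seed(3)
  for (t in 1:10) {
    dets <- data.frame(image_id = 1, class_id = 1,
                       cx = runif(5, 30, 70), cy = runif(5, 30, 70),
                       w = runif(5, 10, 30), h = runif(5, 10, 30),
                       score = runif(5))
    gts2 <- data.frame(image_id = 1, class_id = 1,
                       cx = runif(3, 30, 70), cy = runif(3, 30, 70),
                       w = runif(3, 10, 30), h = runif(3, 10, 30))
    m <- map_range(dets, gts2)
    expect_lte(m[["map5095"]], m[["map50"]] + 1e-12)
  }
})

test_that("fps combines the three stage timings", {
  expect_equal(fps_from_timings(2, 5, 1), 125)
  expect_equal(fps_from_timings(0, 1000, 0), 1)
  expect_equal(fps_from_timings(1, 1, 2), 250)
  expect_error(fps_from_timings(0, 0, 0), "positive")
})
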