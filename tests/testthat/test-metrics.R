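test_that("segmentation metrics follow the confusion-count formulas", {
  truth <- matrix(FALSE, 10, 10)
  truth[3:6, 3:6] <- TRUE
  m <- segmentation_metrics(truth, truth)
  expect_equal(unlist(m[c("precision", "accuracy", "iou", "recall")]),
               c(precision = 1, accuracy = 1, iou = 1, recall = 1))
  # TP 8, FP 2, FN 2, TN 88
  pred <- matrix(FALSE, 10, 10)
  truth2 <- matrix(FALSE, 10, 10)
  truth2[1, 1:10] <- TRUE                      # 10 positives
  pred[1, 1:8] <- TRUE; pred[2, 1:2] <- TRUE   # 8 hits + 2 false alarms
  m2 <- segmentation_metrics(pred, truth2)
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$recall, 0.8)
  expect_equal(m2$iou, 8 / 12, tolerance = 1e-12)
  expect_equal(m2$accuracy, 0.96)
  expect_false(m2$degenerate)
  # degenerate empty prediction and truth
  m3 <- segmentation_metrics(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4))
  expect_true(m3$degenerate)
  expect_equal(m3$iou, 0)
  expect_equal(m3$accuracy, 1)
  expect_error(segmentation_metrics(pred, matrix(FALSE, 2, 2)), "shape")
})

test_that("IOU is bounded by precision and recall; swapping swaps them", {
  set.seed(17)
  for (i in 1:20) {
    pred <- matrix(runif(100) < 0.3, 10, 10)
    truth <- matrix(runif(100) < 0.3, 10, 10)
    m <- segmentation_metrics(pred, truth)
    expect_lte(m$iou, min(m$precision, m$recall) + 1e-12)
    sw <- segmentation_metrics(truth, pred)
    expect_equal(sw$precision, m$recall)
    expect_equal(sw$recall, m$precision)
    expect_equal(sw$iou, m$iou)
    expect_equal(sw$accuracy, m$accuracy)
    expect_true(all(unlist(m[c("precision", "accuracy", "iou",
                               "recall")]) >= 0))
    expect_true(all(unlist(m[c("precision", "accuracy", "iou",
                               "recall")]) <= 1))
  }
})

test_that("micro-averaging pools counts over frames", {
  p1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  t1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  p2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  t2 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  m <- segmentation_metrics(list(p1, p2), list(t1, t2))
  expect_equal(m$counts$tp, 2)
  expect_equal(m$counts$fp, 1)
  expect_equal(m$counts$fn, 1)
  expect_equal(m$precision, 2 / 3)
})

test_that("sharpness measures match hand-computed sums", {
  expect_equal(sharpness_brenner(matrix(c(0, 10, 20, 30), 1, 4)), 800)
  expect_equal(sharpness_roberts(matrix(c(0, 20, 10, 40), 2, 2)), 1700)
  expect_equal(sharpness_smd2(matrix(c(10, 30, 20, 40), 2, 2)), 200)
  cst <- matrix(42, 6, 6)
  expect_equal(sharpness_brenner(cst), 0)
  expect_equal(sharpness_roberts(cst), 0)
  expect_equal(sharpness_smd2(cst), 0)
  expect_error(sharpness_brenner(matrix(1, 5, 2)), "width")
  expect_error(sharpness_roberts(matrix(1:3, 1, 3)), "height")
})

test_that("sharpness is intensity-shift invariant and contrast-quadratic", {
  set.seed(23)
  img <- matrix(runif(64, 0, 200), 8, 8)
  for (f in list(sharpness_brenner, sharpness_roberts, sharpness_smd2)) {
    expect_equal(f(img + 17), f(img))
    expect_equal(f(img * 3), 9 * f(img))
  }
})

test_that("signed SMD2 mode multiplies raw differences", {
  img <- matrix(c(10, 30, 20, 5), 2, 2)
  # (10-30)*(10-20) = 200 signed; |..|*|..| = 200 too
  expect_equal(sharpness_smd2(img, signed = TRUE), 200)
  img2 <- matrix(c(10, 30, 20, 60), 2, 2)
  expect_equal(sharpness_smd2(img2, signed = TRUE),
               (10 - 30) * (10 - 20))
})

test_that("relative difference uses the larger measurement as reference", {
  expect_equal(relative_difference(5, 5), 0)
  expect_equal(relative_difference(1, 4), 0.75)
  expect_error(relative_difference(1, 0), "reference")
})
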