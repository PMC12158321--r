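test_that("global SSIM matches its closed form and is symmetric", {
  a <- matrix(1:20 * 10, 4, 5)
  expect_equal(global_ssim(a, a), 1)
  # two constants: variances and covariance vanish, luminance term remains
  p <- ssim_params()
  expect_equal(global_ssim(matrix(0, 4, 5), matrix(255, 4, 5), p),
               p$C1 / (255^2 + p$C1))
  set.seed(8)
  x <- matrix(runif(30, 0, 255), 5, 6)
  y <- matrix(runif(30, 0, 255), 5, 6)
  expect_equal(global_ssim(x, y), global_ssim(y, x))
  expect_true(abs(global_ssim(x, y)) <= 1)
  expect_error(global_ssim(x, matrix(0, 2, 2)), "shape")
})

test_that("learning-rate schedule is (1 - SSIM)/80, clipped and monotone", {
  expect_equal(learning_rate_from_ssim(1), 0)
  expect_equal(learning_rate_from_ssim(0), 0.0125)
  expect_equal(learning_rate_from_ssim(0.2), 0.01)
  s <- seq(-1, 1, by = 0.05)
  lr <- learning_rate_from_ssim(s)
  expect_true(all(diff(lr) <= 0))
  expect_true(all(lr >= 0 & lr <= 1 / 40))
  # out-of-range similarity is clamped, not an error
  expect_equal(learning_rate_from_ssim(5), 0)
  expect_equal(learning_rate_from_ssim(-3), 1 / 40)
})

test_that("ROI is the tight expanded box over all early detections", {
  m <- matrix(FALSE, 50, 60)
  m[10:20, 30:40] <- TRUE
  roi <- build_roi(list(m), margin = 0)
  expect_equal(roi$rows, c(10L, 21L))
  expect_equal(roi$cols, c(30L, 41L))
  # two separated blobs over two masks -> one covering box
  m2 <- matrix(FALSE, 50, 60)
  m2[40:45, 5:8] <- TRUE
  roi2 <- build_roi(list(m, m2), margin = 2)
  expect_equal(roi2$rows, c(8L, 48L))
  expect_equal(roi2$cols, c(3L, 43L))
  # clipped at the frame border
  roi3 <- build_roi(list(m2), margin = 10)
  expect_equal(roi3$rows, c(30L, 51L))
  expect_equal(roi3$cols, c(1L, 19L))
  expect_warning(roi4 <- build_roi(list(matrix(FALSE, 50, 60))), "whole-frame")
  expect_equal(roi4$rows, c(1L, 51L))
})

test_that("histogram peak counting merges close maxima and clamps", {
  h <- rep(0L, 256)
  h[95:105] <- c(1, 2, 4, 7, 9, 10, 9, 7, 4, 2, 1)
  expect_equal(count_histogram_peaks(h), 1L)
  h2 <- rep(0L, 256)
  h2[51] <- 10; h2[50] <- 3; h2[52] <- 3
  h2[201] <- 8; h2[200] <- 2; h2[202] <- 2
  expect_equal(count_histogram_peaks(h2), 2L)
  h3 <- rep(0L, 256)
  h3[101] <- 10; h3[100] <- 2; h3[102] <- 2
  h3[121] <- 8; h3[120] <- 2; h3[122] <- 2
  expect_equal(count_histogram_peaks(h3), 1L)     # 20 bins apart < 30
  expect_identical(histogram_peaks(h3), 100L)     # the taller one survives
  expect_equal(count_histogram_peaks(rep(0L, 256)), peak_rule()$k_min)
  # invariance to uniform scaling of the counts
  expect_equal(count_histogram_peaks(h2 * 7L), count_histogram_peaks(h2))
  # clamped above
  h4 <- rep(0L, 256)
  h4[seq(10, 250, by = 40)] <- 5
  expect_equal(count_histogram_peaks(h4, peak_rule(k_max = 5L)), 5L)
})

test_that("plateaus collapse to their first bin", {
  h <- rep(0L, 256)
  h[100:110] <- 5L
  h[99] <- 1L; h[111] <- 1L
  expect_identical(histogram_peaks(h), 99L)  # 0-based bin of plateau start
  expect_equal(count_histogram_peaks(h), 1L)
})

test_that("component-count adaptation drops tails, grows seeded, renormalizes", {
  mx <- pixel_mixture(c(0.7, 0.3), c(90, 140), c(25, 100))
  up <- adapt_component_count(mx, 3L, pixel_value = 55)
  expect_length(up$weights, 3L)
  expect_equal(sum(up$weights), 1)
  expect_true(any(abs(as.numeric(up$means) - 55) < 1e-12))
  # growing with peaks seeds the least-covered peak intensity
  up2 <- adapt_component_count(mx, 3L, pixel_value = 55, peaks = c(92, 200))
  expect_true(any(abs(as.numeric(up2$means) - 200) < 1e-12))
  dn <- adapt_component_count(up, 1L)
  expect_length(dn$weights, 1L)
  expect_equal(dn$weights, 1)
  # degenerate request clamps to one component
  z <- adapt_component_count(mx, 0L)
  expect_length(z$weights, 1L)
})

test_that("the adaptive driver keeps mixtures valid and applies the ROI rules", {
  sc <- generate_sequence(synthetic_scene_config(
    height = 36L, width = 44L, n_frames = 60L, n_targets = 2L,
    target_area = c(20, 30), dwell_prob = 0.6, seed = 21))
  run <- itf_gmm(sc$frames, itf_config(warmup_frames = 20L,
                                       hist_window = 30L, roi_margin = 3L))
  model <- run$model
  expect_true(all(model$kcount >= 1L & model$kcount <= 5L))
  sums <- vapply(seq_along(model$kcount), function(p)
    sum(model$weights[p, seq_len(model$kcount[p])]), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  # outside the ROI the component count is pinned at 2
  rpix <- irseg:::roi_pixel_index(run$roi, model$height)
  out <- setdiff(seq_along(model$kcount), rpix)
  expect_true(all(model$kcount[out] == 2L))
  # masks exist for every frame and warmup frames are flagged
  expect_length(run$masks, 60L)
  expect_equal(run$warmup, 1:20)
  expect_error(itf_gmm(sc$frames[1:10], itf_config(warmup_frames = 20L)),
               "warmup")
})

test_that("disabling both adaptive features reproduces the plain driver", {
  sc <- tiny_scene(seed = 12, n_frames = 25L)
  run <- itf_gmm(sc$frames, itf_config(warmup_frames = 10L,
                                       adapt_lr = FALSE, adapt_k = FALSE))
  plain <- background_subtract(sc$frames)
  for (t in seq_along(plain))
    expect_identical(run$masks[[t]], plain[[t]])
})
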