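test_that("initialization gives equal weights, seeded means and set variance", {
  f <- matrix(c(10, 20, 30, 200), 2, 2)
  m <- gmm_background(f, k_init = 2,
                      params = gmm_params(init_variance = 225))
  expect_equal(m$weights[, 1:2], matrix(0.5, 4, 2))
  expect_equal(m$means[, 1], as.numeric(f))
  expect_true(all(m$vars[, 1:2] == 225))
  m1 <- gmm_background(f, k_init = 1)
  expect_equal(m1$weights[, 1], rep(1, 4))
  expect_error(gmm_background(f, k_init = 0), "k_init")
  expect_error(gmm_background("nope"), "numeric")
})

test_that("component matching follows the sigma-multiplier rule in rank order", {
  mx <- pixel_mixture(1, 100, 100)  # sigma = 10
  expect_identical(match_component(120, mx, 2.5), 1L)
  expect_identical(match_component(126, mx, 2.5), NA_integer_)
  two <- pixel_mixture(c(0.5, 0.5), c(50, 200), c(25, 25))
  expect_identical(match_component(52, two), 1L)
  expect_identical(match_component(199, two), 2L)
})

test_that("mixture updates reproduce the exponential update arithmetic", {
  # matched weight: (1-alpha) w + alpha, checked before normalization via a
  # single-component mixture (normalization then forces 1)
  mx <- pixel_mixture(c(0.4, 0.6), c(100, 50), c(100, 100))
  up <- update_mixture(mx, 1L, 120, 0.1)
  # raw weights 0.46 and 0.54, already summing to 1
  expect_equal(sort(up$weights), sort(c(0.46, 0.54)))
  # unmatched decay (1-alpha) w
  expect_true(any(abs(up$weights - 0.54) < 1e-12))
  # mean update with rho = alpha
  mx2 <- pixel_mixture(1, 100, 100)
  up2 <- update_mixture(mx2, 1L, 120, 0.5)
  expect_equal(as.numeric(up2$means), 110)
  expect_error(update_mixture(mx2, 1L, 120, 1.5), "alpha")
})

test_that("no-match replaces the lowest-ranked component and renormalizes", {
  mx <- pixel_mixture(c(0.7, 0.3), c(100, 60), c(25, 25))
  up <- update_mixture(mx, NA_integer_, 250, 0.02,
                       gmm_params(replacement_weight = 0.05,
                                  init_variance = 225))
  expect_equal(sum(up$weights), 1)
  expect_true(any(abs(as.numeric(up$means) - 250) < 1e-12))
  expect_true(any(up$vars == 225))
  # the surviving old component is the previously top-ranked one
  expect_true(any(abs(as.numeric(up$means) - 100) < 1e-12))
  expect_false(any(abs(as.numeric(up$means) - 60) < 1e-12))
})

test_that("background prefix selection is the minimal cumulative-weight prefix", {
  expect_identical(select_background(c(0.6, 0.3, 0.1), T = 0.5), 1L)
  expect_identical(select_background(c(0.5, 0.3, 0.2), T = 0.7), 2L)
  expect_identical(select_background(c(0.4, 0.3, 0.3), T = 1.0), 3L)
  unsorted <- pixel_mixture(c(0.2, 0.8), c(1, 2), c(100, 100))
  expect_error(select_background(unsorted, 0.7), "sorted")
})

test_that("a stationary scene is absorbed into the background", {
  frames <- replicate(12, matrix(77, 6, 6), simplify = FALSE)
  masks <- background_subtract(as_frame_sequence(frames))
  expect_false(any(masks[[12]]))
})

test_that("an intensity jump beyond the match bound is foreground", {
  model <- gmm_background(matrix(50, 3, 3), k_init = 2)
  for (i in 1:5) step_frame(model, matrix(50, 3, 3))
  f <- matrix(50, 3, 3); f[2, 2] <- 250
  mask <- step_frame(model, f)
  expect_true(mask[2, 2])
  expect_equal(sum(mask), 1L)
})

test_that("weights stay normalized and sorted after every step", {
  set.seed(42)
  model <- gmm_background(matrix(runif(25, 0, 255), 5, 5), k_init = 3)
  for (t in 1:30) {
    step_frame(model, matrix(runif(25, 0, 255), 5, 5), alpha = 0.05)
    sums <- rowSums(model$weights[, 1:3])
    expect_true(all(abs(sums - 1) < 1e-9))
    key <- model$weights[, 1:3] / model$vars[, 1:3]
    expect_true(all(key[, 1] >= key[, 2] - 1e-12 &
                    key[, 2] >= key[, 3] - 1e-12))
  }
})

test_that("alpha = 0 freezes all model state except the frame counter", {
  set.seed(3)
  model <- gmm_background(matrix(runif(16, 0, 255), 4, 4), k_init = 3)
  step_frame(model, matrix(runif(16, 0, 255), 4, 4))
  before <- list(w = model$weights + 0, mu = model$means + 0,
                 v = model$vars + 0, k = model$kcount + 0L,
                 frames = model$frames_seen)
  step_frame(model, matrix(runif(16, 0, 255), 4, 4), alpha = 0)
  expect_identical(model$weights, before$w)
  expect_identical(model$means, before$mu)
  expect_identical(model$vars, before$v)
  expect_identical(model$kcount, before$k)
  expect_identical(model$frames_seen, before$frames + 1L)
})

test_that("matched-component weight is non-decreasing on constant video", {
  model <- gmm_background(matrix(100, 2, 2), k_init = 3)
  prev <- model$weights[1, 1]
  for (t in 1:20) {
    step_frame(model, matrix(100, 2, 2), alpha = 0.05)
    expect_gte(model$weights[1, 1], prev - 1e-12)
    prev <- model$weights[1, 1]
  }
  expect_gt(prev, 1 / 3)
})

test_that("grid model matches the straight-line scalar reference", {
  set.seed(99)
  for (rep in 1:10) {
    len <- sample(10:50, 1)
    history <- sample(0:255, len, replace = TRUE)
    expect_identical(grid_pixel_gmm(history),
                     oracle_pixel_gmm(history))
  }
  # and on a scripted 4x4 grid, pixel by pixel
  set.seed(100)
  frames <- replicate(10, matrix(sample(0:255, 16, TRUE), 4, 4),
                      simplify = FALSE)
  masks <- background_subtract(as_frame_sequence(frames))
  for (r in 1:4) for (c in 1:4) {
    hist <- vapply(frames, function(f) f[r, c], numeric(1))
    expect_identical(vapply(masks, function(m) m[r, c], logical(1)),
                     oracle_pixel_gmm(hist))
  }
})

test_that("model state round-trips through a checkpoint", {
  model <- gmm_background(matrix(1:16 * 10, 4, 4), k_init = 2)
  step_frame(model, matrix(80, 4, 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_gmm_background(model, path)
  back <- load_gmm_background(path)
  expect_identical(back$weights, model$weights)
  expect_identical(back$means, model$means)
  expect_identical(back$frames_seen, model$frames_seen)
})

test_that("the 3-channel mode matches jointly across channels", {
  p <- gmm_params(channels = 3L)
  f1 <- array(100, dim = c(3, 3, 3))
  model <- gmm_background(f1, k_init = 2, params = p)
  for (i in 1:5) step_frame(model, f1)
  expect_false(any(step_frame(model, f1)))
  # one channel far out of bound makes the pixel foreground
  f2 <- f1
  f2[2, 2, 3] <- 250
  mask <- step_frame(model, f2)
  expect_true(mask[2, 2])
  expect_equal(sum(mask), 1L)
  # scalar matching agrees: all channels must sit within the bound
  mx <- pixel_mixture(1, matrix(c(100, 100, 100), 3, 1), 100)
  expect_identical(match_component(c(110, 95, 100), mx), 1L)
  expect_identical(match_component(c(110, 95, 180), mx), NA_integer_)
})
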