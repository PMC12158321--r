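test_that("the network maps an admissible input to per-pixel probabilities", {
  set.seed(51)
  spec <- conunet_spec(depth = 2L, base_width = 4L, input_size = 32L)
  net <- conunet(spec)
  x <- matrix(runif(32 * 32), 1L, 32 * 32)
  fw <- conunet_forward(net, x, 32L, 32L)
  expect_identical(dim(fw$prob), c(1L, 32L * 32L))
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  expect_error(conunet_forward(net, matrix(runif(30 * 30), 1L), 30L, 30L),
               "divisible")
  expect_error(conunet_spec(depth = 3L, input_size = 36L), "divisible")
})

test_that("encoder widths double per stage and strided mode has no pooling", {
  spec <- conunet_spec(depth = 4L, base_width = 64L)
  expect_equal(conunet_widths(spec), c(64L, 128L, 256L, 512L, 1024L))
  kinds <- vapply(irseg:::conunet_layers(spec), `[[`, "", "kind")
  expect_false(any(kinds == "pool"))
  base <- conunet_spec(depth = 4L, base_width = 64L, subsample = "maxpool2")
  expect_equal(sum(vapply(irseg:::conunet_layers(base), `[[`, "", "kind")
                   == "pool"), 4)
})

test_that("FLOPs accounting follows 2 * Cin * k^2 * Cout * Hout * Wout", {
  # smallest instantiable network: hand-sum every layer at 4x4 input
  spec <- conunet_spec(depth = 1L, base_width = 1L, input_size = 4L)
  # enc1_conv1 1->1@4x4, enc1_conv2 1->1@4x4, enc1_down 1->1@2x2,
  # bott 1->2@2x2 + 2->2@2x2, up 2->1@4x4 (2x2 kernel),
  # dec convs 2->1@4x4 + 1->1@4x4, head 1x1@4x4
  manual <- 2 * (9 * 16 + 9 * 16 + 9 * 4 +
                 1 * 9 * 2 * 4 + 2 * 9 * 2 * 4 +
                 2 * 4 * 1 * 16 +
                 2 * 9 * 1 * 16 + 1 * 9 * 1 * 16 +
                 1 * 1 * 16)
  expect_equal(count_flops(spec) * 1e9, manual)
  # bias adds one operation per output element of each layer
  with_bias <- count_flops(spec, include_bias = TRUE) * 1e9
  expect_equal(with_bias - manual,
               16 + 16 + 4 + 2 * 4 + 2 * 4 + 16 + 16 + 16 + 16)
})

test_that("strided subsampling always costs more than pooling", {
  for (depth in 2:4) for (bw in c(8L, 16L)) {
    con <- conunet_spec(depth = depth, base_width = bw, input_size = 64L)
    pool <- conunet_spec(depth = depth, base_width = bw, input_size = 64L,
                         subsample = "maxpool2")
    expect_gt(count_flops(con), count_flops(pool))
  }
})

test_that("the calibrated reference pair reproduces the published complexity", {
  u <- count_flops(unet_reference_spec("unet"))
  cu <- count_flops(unet_reference_spec("conunet"))
  expect_lt(abs(u - 60.24) / 60.24, 0.02)
  expect_lt(abs(cu - 63.44) / 63.44, 0.02)
  expect_gt(cu, u)
})

test_that("training descends, is seed-reproducible, and can overfit one pair", {
  set.seed(53)
  img <- matrix(60, 32, 32)
  img[10:20, 8:16] <- 110
  msk <- matrix(FALSE, 32, 32)
  msk[10:20, 8:16] <- TRUE
  imgs <- list(img, t(img), img[32:1, ], img[, 32:1])
  msks <- list(msk, t(msk), msk[32:1, ], msk[, 32:1])
  cfg <- training_config(epochs = 40L, batch_size = 2L, lr = 2e-3,
                         input_size = 32L, split = 1, seed = 7)
  net <- with_seed(7, conunet(conunet_spec(depth = 2L, base_width = 6L,
                                           input_size = 32L)))
  net <- train_conunet(net, imgs, msks, cfg)
  h <- net$loss_history$train
  expect_lt(tail(h, 1), h[1])
  net2 <- with_seed(7, conunet(conunet_spec(depth = 2L, base_width = 6L,
                                            input_size = 32L)))
  net2 <- train_conunet(net2, imgs, msks, cfg)
  expect_identical(net$loss_history$train, net2$loss_history$train)
  # overfit check on the training pair itself
  pred <- predict_mask(net, img)
  expect_gt(segmentation_metrics(pred, msk)$iou, 0.9)
  # held-out variant of the same blob family
  img2 <- matrix(60, 32, 32)
  img2[5:14, 15:24] <- 110
  msk2 <- matrix(FALSE, 32, 32)
  msk2[5:14, 15:24] <- TRUE
  expect_gt(segmentation_metrics(predict_mask(net, img2), msk2)$iou, 0.5)
})

test_that("prediction validates state, thresholds, and restores geometry", {
  net <- conunet(conunet_spec(depth = 2L, base_width = 4L, input_size = 16L))
  expect_error(predict_mask(net, matrix(0, 16, 16)), "untrained")
  # force a constant probability map of 0.4: zero weights, bias = logit(0.4)
  net$trained <- TRUE
  net$input_size <- 16L
  net$params$head$W[] <- 0
  net$params$head$b[] <- log(0.4 / 0.6)
  frame <- matrix(runif(20 * 24, 0, 255), 20, 24)
  m <- predict_mask(net, frame, threshold = 0.5)
  expect_identical(dim(m), dim(frame))
  expect_false(any(m))
  expect_true(all(predict_mask(net, frame, threshold = 0.3)))
})

test_that("training rejects empty or non-binary data", {
  net <- conunet(conunet_spec(depth = 2L, base_width = 4L, input_size = 16L))
  expect_error(train_conunet(net, list(), list()), "at least one")
  img <- matrix(0, 16, 16)
  expect_error(train_conunet(net, list(img), list(img + 0.5)), "binary")
})

test_that("checkpoints round-trip the spec and weights", {
  set.seed(59)
  net <- conunet(conunet_spec(depth = 2L, base_width = 4L, input_size = 16L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_conunet(net, path)
  back <- load_conunet(path)
  expect_identical(back$params, net$params)
  expect_identical(back$spec, net$spec)
  x <- matrix(runif(256), 1, 256)
  expect_equal(conunet_forward(back, x, 16L, 16L)$prob,
               conunet_forward(net, x, 16L, 16L)$prob)
})
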