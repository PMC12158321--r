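#' Parameters of the Gaussian-mixture background model
#'
#' @param default_alpha default learning rate of the exponential updates
#'   (dimensionless, > 0). A configured value of -1 maps to this default.
#' @param T background proportion threshold: the smallest prefix of
#'   components (in weight/variance rank order) whose cumulative weight
#'   reaches `T` is treated as background. Must lie in `[0.5, 1]`.
#' @param match_multiplier a pixel matches a component when its value lies
#'   within `match_multiplier * sigma` of the component mean on every channel
#'   (default 2.5)
#' @param init_variance initial/replacement component variance (intensity^2)
#' @param replacement_weight weight given to a replacement component when no
#'   component matches
#' @param variance_floor lower bound on component variances, preventing
#'   degenerate sigma -> 0 on constant video
#' @param channels 1 (grayscale, default) or 3; channels share one variance
#' @param rho_mode second-order rate for the mean/variance updates:
#'   `"alpha"` uses rho = alpha (default), `"density"` uses
#'   rho = alpha * eta(value | mu, sigma)
#' @param k_max maximum components kept per pixel
#' @return a `gmm_params` list
#' @export
gmm_params <- function(default_alpha = 0.005, T = 0.7,
                       match_multiplier = 2.5, init_variance = 225,
                       replacement_weight = 0.05, variance_floor = 1,
                       channels = 1L, rho_mode = c("alpha", "density"),
                       k_max = 5L) {
  rho_mode <- match.arg(rho_mode)
  if (identical(default_alpha, -1)) default_alpha <- 0.005
  stopifnot(default_alpha > 0, default_alpha <= 1,
            T >= 0.5, T <= 1.0,
            match_multiplier > 0, init_variance > 0,
            replacement_weight > 0, variance_floor > 0,
            channels %in% c(1L, 3L), k_max >= 1L)
  structure(list(default_alpha = default_alpha, T = T,
                 match_multiplier = match_multiplier,
                 init_variance = init_variance,
                 replacement_weight = replacement_weight,
                 variance_floor = variance_floor,
                 channels = as.integer(channels), rho_mode = rho_mode,
                 k_max = as.integer(k_max)),
            class = "gmm_params")
}

frame_to_pixels <- function(frame, channels) {
  d <- frame_shape(frame)
  if (d[3L] != channels)
    stop("frame has ", d[3L], " channel(s); model expects ", channels)
  matrix(as.numeric(frame), d[1L] * d[2L], channels)
}

#' Initialize a per-pixel Gaussian-mixture background model
#'
#' Every pixel receives `k_init` components with equal weights `1/k_init` and
#' variance `init_variance`; the first component mean is the pixel's value in
#' `first_frame`, the remaining means start at 0.
#'
#' The returned model has reference semantics (an environment):
#' [step_frame()] updates it in place.
#'
#' @param first_frame numeric `H x W` matrix (or `H x W x 3` array) with
#'   intensities in `[0, 255]`
#' @param k_init initial number of components per pixel (>= 1)
#' @param params a [gmm_params()]
#' @return an object of class `gmm_background`
#' @export
gmm_background <- function(first_frame, k_init = 3L, params = gmm_params()) {
  if (!is.numeric(first_frame) || is.null(dim(first_frame)))
    stop("first_frame must be a numeric matrix or H x W x 3 array")
  if (k_init < 1L) stop("k_init must be >= 1")
  if (anyNA(first_frame) || min(first_frame) < 0 || max(first_frame) > 255)
    stop("first_frame intensities must lie in [0, 255]")
  d <- frame_shape(first_frame)
  nch <- params$channels
  px <- frame_to_pixels(first_frame, nch)
  n <- nrow(px)
  kmax <- max(params$k_max, k_init)
  m <- new.env(parent = emptyenv())
  m$weights <- matrix(0, n, kmax)
  m$weights[, seq_len(k_init)] <- 1 / k_init
  m$means <- matrix(0, n, kmax * nch)
  m$means[, seq_len(nch)] <- px
  m$vars <- matrix(params$variance_floor, n, kmax)
  m$vars[, seq_len(k_init)] <- params$init_variance
  m$kcount <- rep.int(as.integer(k_init), n)
  m$height <- d[1L]; m$width <- d[2L]; m$channels <- nch
  m$params <- params
  m$frames_seen <- 1L
  class(m) <- "gmm_background"
  m
}

#' @export
print.gmm_background <- function(x, ...) {
  cat(sprintf(paste0("<gmm_background> %d x %d, %d channel(s), ",
                     "K in [%d, %d], %d frame(s) seen\n"),
              x$height, x$width, x$channels,
              min(x$kcount), max(x$kcount), x$frames_seen))
  invisible(x)
}

#' Classify one frame and update the background model
#'
#' Each pixel is compared against its mixture in weight/variance rank order
#' (the `2.5 sigma` rule); a matching component ranked inside the background
#' prefix marks the pixel background, anything else foreground. Matched
#' components are pulled toward the pixel value at the learning rate, all
#' other weights decay, and when nothing matches the lowest-ranked component
#' is replaced by a fresh one centred on the pixel. Weights are renormalized
#' and components re-sorted after every update. A learning rate of exactly 0
#' freezes the model (only the frame counter advances).
#'
#' @param model a [gmm_background()] (modified in place)
#' @param frame frame matching the model grid
#' @param alpha learning rate: `NULL` (model default), a scalar, or an
#'   `H x W` matrix of per-pixel rates
#' @param update if `FALSE`, classify only (no state change)
#' @return logical `H x W` foreground mask
#' @export
step_frame <- function(model, frame, alpha = NULL, update = TRUE) {
  stopifnot(inherits(model, "gmm_background"))
  d <- frame_shape(frame)
  if (d[1L] != model$height || d[2L] != model$width)
    stop("frame shape does not match the model grid")
  px <- frame_to_pixels(frame, model$channels)
  p <- model$params
  if (is.null(alpha)) alpha <- p$default_alpha
  if (is.matrix(alpha)) {
    if (!identical(dim(alpha), c(model$height, model$width)))
      stop("per-pixel alpha must match the frame shape")
    alpha <- as.numeric(alpha)
  }
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha must lie in [0, 1]")
  mask <- gmm_step_cpp(model$weights, model$means, model$vars, model$kcount,
                       px, as.numeric(alpha), p$T, p$match_multiplier,
                       p$init_variance, p$replacement_weight,
                       p$variance_floor,
                       if (p$rho_mode == "density") 1L else 0L,
                       isTRUE(update))
  if (isTRUE(update)) model$frames_seen <- model$frames_seen + 1L
  matrix(mask == 1L, model$height, model$width)
}

#' Plain GMM background subtraction over a frame sequence
#'
#' Initializes the model on the first frame and steps through the rest with a
#' fixed learning rate — the unmodified baseline against which the adaptive
#' variants are compared.
#'
#' @param frames a frame sequence (see [as_frame_sequence()])
#' @param params a [gmm_params()]
#' @param k_init initial components per pixel
#' @param alpha fixed learning rate (default: `params$default_alpha`)
#' @return list of logical masks, one per frame (the first is all-background),
#'   with the final `model` attached as an attribute
#' @export
background_subtract <- function(frames, params = gmm_params(), k_init = 3L,
                                alpha = NULL) {
  frames <- as_frame_sequence(frames)
  model <- gmm_background(frames[[1L]], k_init = k_init, params = params)
  masks <- vector("list", length(frames))
  masks[[1L]] <- matrix(FALSE, model$height, model$width)
  for (t in seq_along(frames)[-1L])
    masks[[t]] <- step_frame(model, frames[[t]], alpha = alpha)
  attr(masks, "model") <- model
  masks
}

# ---- single-pixel mixture operations ---------------------------------------

#' A single pixel's mixture
#'
#' Plain-R representation of one pixel's component list, ordered by
#' weight/variance descending, used by the scalar mixture operations and for
#' inspecting grid models.
#'
#' @param weights component weights (sum 1)
#' @param means component means; a numeric vector, or an `nch x K` matrix for
#'   multi-channel pixels
#' @param vars component variances (shared across channels)
#' @return a `pixel_mixture` list
#' @export
pixel_mixture <- function(weights, means, vars) {
  if (is.null(dim(means))) means <- matrix(means, 1L, length(means))
  K <- length(weights)
  stopifnot(K >= 1L, ncol(means) == K, length(vars) == K, all(vars > 0),
            all(weights >= 0))
  structure(list(weights = weights, means = means, vars = vars),
            class = "pixel_mixture")
}

#' Extract one pixel's mixture from a grid model
#' @param model a [gmm_background()]
#' @param row,col pixel coordinates
#' @return a [pixel_mixture()]
#' @export
mixture_at <- function(model, row, col) {
  p <- (col - 1L) * model$height + row
  K <- model$kcount[p]
  nch <- model$channels
  idx <- seq_len(K)
  mu <- matrix(model$means[p, seq_len(K * nch)], nch, K)
  pixel_mixture(model$weights[p, idx], mu, model$vars[p, idx])
}

#' First matching component of a pixel value
#'
#' Returns the index of the first component, in rank order, whose mean lies
#' within `multiplier * sigma` of the value on every channel, or `NA` when no
#' component matches.
#'
#' @param pixel_value scalar intensity (or length-`nch` vector)
#' @param mixture a [pixel_mixture()]
#' @param multiplier match bound in standard deviations (default 2.5)
#' @return component index, or `NA_integer_`
#' @export
match_component <- function(pixel_value, mixture, multiplier = 2.5) {
  stopifnot(inherits(mixture, "pixel_mixture"), multiplier > 0)
  if (length(mixture$weights) == 0L) stop("empty mixture")
  sig <- sqrt(mixture$vars)
  for (i in seq_along(mixture$weights)) {
    if (all(abs(pixel_value - mixture$means[, i]) <= multiplier * sig[i]))
      return(i)
  }
  NA_integer_
}

#' Update a pixel mixture with one observation
#'
#' Applies the exponential weight/mean/variance updates to the matched
#' component, decays unmatched weights, replaces the lowest-ranked component
#' on a no-match, then renormalizes and re-sorts (stable, by
#' weight/variance descending).
#'
#' @param mixture a [pixel_mixture()]
#' @param matched index from [match_component()], or `NA` for no-match
#' @param pixel_value observed intensity
#' @param alpha learning rate in `[0, 1]`
#' @param params a [gmm_params()] supplying the replacement weight/variance,
#'   variance floor and rho mode
#' @return the updated [pixel_mixture()]
#' @export
update_mixture <- function(mixture, matched, pixel_value, alpha,
                           params = gmm_params()) {
  stopifnot(inherits(mixture, "pixel_mixture"))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  w <- mixture$weights; mu <- mixture$means; v <- mixture$vars
  nch <- nrow(mu)
  if (alpha == 0) return(mixture)
  if (!is.na(matched)) {
    i <- matched
    d2 <- sum((pixel_value - mu[, i])^2)
    rho <- if (params$rho_mode == "density") {
      min(1, alpha * (2 * pi * v[i])^(-nch / 2) * exp(-d2 / (2 * v[i])))
    } else alpha
    w <- (1 - alpha) * w
    w[i] <- w[i] + alpha
    mu[, i] <- mu[, i] + rho * (pixel_value - mu[, i])
    v[i] <- max((1 - rho) * v[i] + rho * d2, params$variance_floor)
  } else {
    w <- (1 - alpha) * w
    r <- length(w)
    w[r] <- params$replacement_weight
    mu[, r] <- pixel_value
    v[r] <- max(params$init_variance, params$variance_floor)
  }
  w <- w / sum(w)
  ord <- order(-(w / v))  # stable: ties keep original index order
  pixel_mixture(w[ord], mu[, ord, drop = FALSE], v[ord])
}

#' Background prefix length of a sorted mixture
#'
#' The smallest number of leading components (ranked by weight/variance
#' descending) whose cumulative weight reaches the background proportion
#' threshold `T`.
#'
#' @param mixture a [pixel_mixture()], or a numeric vector of sorted weights
#' @param T background proportion threshold in `[0.5, 1]`
#' @return integer `B` with `1 <= B <= K`
#' @export
select_background <- function(mixture, T = 0.7) {
  stopifnot(T >= 0.5, T <= 1.0)
  w <- if (inherits(mixture, "pixel_mixture")) mixture$weights else mixture
  if (inherits(mixture, "pixel_mixture")) {
    key <- w / mixture$vars
    if (any(diff(key) > 1e-9)) stop("mixture is not sorted by weight/variance")
  }
  cw <- cumsum(w)
  B <- which(cw >= T - 1e-12)
  if (length(B) == 0L) length(w) else B[1L]
}

#' Save / load a background model
#'
#' Checkpoints the full mixture state to an RDS container.
#'
#' @param model a [gmm_background()]
#' @param path file path
#' @return `load_gmm_background()` returns the restored model
#' @export
save_gmm_background <- function(model, path) {
  stopifnot(inherits(model, "gmm_background"))
  saveRDS(mget(ls(model), envir = model), path)
  invisible(path)
}

#' @rdname save_gmm_background
#' @export
load_gmm_background <- function(path) {
  fields <- readRDS(path)
  m <- list2env(fields, parent = emptyenv())
  class(m) <- "gmm_background"
  m
}
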