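#' SSIM stabilization constants
#'
#' @param L dynamic range of the intensities (default 255)
#' @param C1,C2 stabilization constants; defaults `(0.01 L)^2` and
#'   `(0.03 L)^2`, the customary choices, keeping both denominators positive
#' @return an `ssim_params` list
#' @export
ssim_params <- function(L = 255, C1 = (0.01 * L)^2, C2 = (0.03 * L)^2) {
  stopifnot(C1 > 0, C2 > 0)
  structure(list(C1 = C1, C2 = C2, L = L), class = "ssim_params")
}

#' Global structural similarity of two images
#'
#' Single-window SSIM computed from the whole-region means, variances and
#' covariance (no sliding window):
#' `(2 mu_j mu_k + C1)(2 cov + C2) / ((mu_j^2 + mu_k^2 + C1)(var_j + var_k + C2))`.
#' Identical images score 1; the value is symmetric in its arguments and lies
#' in `[-1, 1]`.
#'
#' @param img_a,img_b numeric matrices of identical shape
#' @param params an [ssim_params()]
#' @return scalar similarity
#' @export
global_ssim <- function(img_a, img_b, params = ssim_params()) {
  if (length(img_a) == 0L) stop("images must be nonempty")
  check_same_shape(img_a, img_b, "images")
  a <- as.numeric(img_a); b <- as.numeric(img_b)
  n <- length(a)
  ma <- mean(a); mb <- mean(b)
  va <- sum((a - ma)^2) / n
  vb <- sum((b - mb)^2) / n
  cab <- sum((a - ma) * (b - mb)) / n
  ((2 * ma * mb + params$C1) * (2 * cab + params$C2)) /
    ((ma^2 + mb^2 + params$C1) * (va + vb + params$C2))
}

#' Learning rate from inter-frame similarity
#'
#' `alpha = (1 - SSIM) / 80`, clipped to `[0, 1]`: near-identical consecutive
#' frames (slowly moving or dwelling targets) freeze the background model,
#' while large scene changes speed adaptation up. The range of the schedule
#' is `[0, 1/40]`.
#'
#' @param ssim similarity value; clamped to `[-1, 1]`
#' @return learning rate
#' @export
learning_rate_from_ssim <- function(ssim) {
  s <- pmin(pmax(ssim, -1), 1)
  pmin(pmax((1 - s) / 80, 0), 1)
}

#' Fixed region of interest from early detections
#'
#' The tight axis-aligned bounding box of the union of all foreground pixels
#' in the warmup masks, expanded by `margin` pixels and clipped to the frame.
#' The box is half-open: `rows[1] <= r < rows[2]`. When no pixel was detected
#' the whole frame is returned with a warning.
#'
#' @param early_masks list of binary masks of one shape
#' @param margin expansion in pixels (default 0)
#' @return an object of class `roi`: list with half-open `rows` and `cols`
#' @export
build_roi <- function(early_masks, margin = 0L) {
  if (length(early_masks) == 0L) stop("need at least one mask")
  u <- as_mask(early_masks[[1L]])
  for (m in early_masks[-1L]) {
    m <- as_mask(m)
    check_same_shape(u, m, "masks")
    u <- u | m
  }
  h <- nrow(u); w <- ncol(u)
  if (!any(u)) {
    warning("no detections in early masks; falling back to whole-frame ROI")
    return(structure(list(rows = c(1L, h + 1L), cols = c(1L, w + 1L)),
                     class = "roi"))
  }
  rr <- range(which(rowSums(u) > 0))
  cc <- range(which(colSums(u) > 0))
  structure(list(
    rows = c(max(1L, rr[1L] - margin), min(h + 1L, rr[2L] + margin + 1L)),
    cols = c(max(1L, cc[1L] - margin), min(w + 1L, cc[2L] + margin + 1L))),
    class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows [%d, %d) x cols [%d, %d)\n",
              x$rows[1L], x$rows[2L], x$cols[1L], x$cols[2L]))
  invisible(x)
}

roi_crop <- function(frame, roi) {
  frame[roi$rows[1L]:(roi$rows[2L] - 1L), roi$cols[1L]:(roi$cols[2L] - 1L),
        drop = FALSE]
}

roi_pixel_index <- function(roi, height) {
  rows <- roi$rows[1L]:(roi$rows[2L] - 1L)
  cols <- roi$cols[1L]:(roi$cols[2L] - 1L)
  as.vector(outer(rows, (cols - 1L) * height, `+`))
}

#' Peak-counting rule for temporal histograms
#'
#' @param merge_distance neighbouring maxima closer than this many bins are
#'   merged into one peak, keeping the taller (default 30)
#' @param k_min,k_max clamps applied to the resulting component count
#' @return a `peak_rule` list
#' @export
peak_rule <- function(merge_distance = 30L, k_min = 1L, k_max = 5L) {
  stopifnot(merge_distance >= 1L, k_min >= 1L, k_min <= k_max)
  structure(list(merge_distance = as.integer(merge_distance),
                 k_min = as.integer(k_min), k_max = as.integer(k_max)),
            class = "peak_rule")
}

#' Surviving peaks of a 256-bin temporal histogram
#'
#' Local maxima (plateaus collapse to their first bin), greedily merged left
#' to right whenever two neighbouring maxima are closer than
#' `merge_distance`, keeping the taller (ties keep the left one).
#'
#' @param hist integer vector of 256 nonnegative bin counts
#' @param merge_distance merge threshold in bins
#' @return integer vector of surviving peak intensities (0-255)
#' @export
histogram_peaks <- function(hist, merge_distance = 30L) {
  if (length(hist) != 256L || any(hist < 0))
    stop("hist must be 256 nonnegative bin counts")
  peaks_cpp(as.integer(hist), as.integer(merge_distance))
}

#' Component count from a temporal histogram
#'
#' The number of surviving peaks of [histogram_peaks()], clamped to
#' `[k_min, k_max]`; an all-zero histogram returns `k_min`. The count is
#' invariant to uniform scaling of the bin counts.
#'
#' @param hist integer vector of 256 bin counts
#' @param rule a [peak_rule()]
#' @return integer component count
#' @export
count_histogram_peaks <- function(hist, rule = peak_rule()) {
  p <- length(histogram_peaks(hist, rule$merge_distance))
  min(max(p, rule$k_min), rule$k_max)
}

#' Resize a pixel mixture to a target component count
#'
#' Dropping always removes the lowest-ranked components; growing appends
#' fresh components with the replacement weight and initial variance, centred
#' on the least-covered histogram peak when peak intensities are supplied
#' (the peak farthest from all existing means in units of their sigma),
#' otherwise on the current pixel value. Weights are renormalized.
#'
#' @param mixture a [pixel_mixture()]
#' @param target_k requested component count (clamped to >= 1)
#' @param params a [gmm_params()]
#' @param pixel_value fallback mean for new components
#' @param peaks optional numeric vector of surviving peak intensities
#' @return the resized [pixel_mixture()]
#' @export
adapt_component_count <- function(mixture, target_k, params = gmm_params(),
                                  pixel_value = 0, peaks = NULL) {
  stopifnot(inherits(mixture, "pixel_mixture"))
  target_k <- max(1L, as.integer(target_k))
  w <- mixture$weights; mu <- mixture$means; v <- mixture$vars
  K <- length(w)
  if (K > target_k) {
    keep <- seq_len(target_k)
    w <- w[keep]; mu <- mu[, keep, drop = FALSE]; v <- v[keep]
  } else if (K < target_k) {
    for (j in seq_len(target_k - K)) {
      seed <- least_covered_peak(peaks, mu, v, pixel_value)
      w <- c(w, params$replacement_weight)
      mu <- cbind(mu, seed)
      v <- c(v, max(params$init_variance, params$variance_floor))
    }
  }
  w <- w / sum(w)
  ord <- order(-(w / v))
  pixel_mixture(w[ord], mu[, ord, drop = FALSE], v[ord])
}

least_covered_peak <- function(peaks, mu, v, fallback) {
  if (is.null(peaks) || length(peaks) == 0L) return(fallback)
  sig <- sqrt(v)
  score <- vapply(peaks, function(pk)
    min(abs(pk - as.numeric(mu[1L, ])) / sig), numeric(1L))
  peaks[which.max(score)]
}

# grid form: set per-pixel component counts on a gmm_background in place
set_component_count <- function(model, target, seeds = NULL,
                                pixels = seq_len(length(model$kcount))) {
  p <- model$params
  target <- pmin(pmax(as.integer(target), 1L), p$k_max)
  stopifnot(length(target) == length(pixels))
  cur <- model$kcount[pixels]
  changed <- which(cur != target)
  if (length(changed) == 0L) return(invisible(model))
  nch <- model$channels
  shrink <- changed[target[changed] < cur[changed]]
  if (length(shrink))
    model$kcount[pixels[shrink]] <- target[shrink]
  grow <- changed[target[changed] > cur[changed]]
  while (length(grow)) {
    gp <- pixels[grow]
    slot <- model$kcount[gp] + 1L
    model$weights[cbind(gp, slot)] <- p$replacement_weight
    model$vars[cbind(gp, slot)] <- max(p$init_variance, p$variance_floor)
    sv <- if (is.null(seeds)) rep(0, length(grow)) else seeds[grow]
    for (c in seq_len(nch))
      model$means[cbind(gp, (slot - 1L) * nch + c)] <- sv
    model$kcount[gp] <- slot
    grow <- grow[model$kcount[pixels[grow]] < target[grow]]
  }
  gmm_normalize_sort_cpp(model$weights, model$means, model$vars,
                         model$kcount, as.integer(pixels[changed]), nch)
  invisible(model)
}

#' Configuration of the adaptive (ITF) background model
#'
#' @param warmup_frames frames processed with the plain model before the ROI
#'   is frozen (default 100)
#' @param roi_margin ROI expansion in pixels (default 5)
#' @param hist_window rolling temporal-histogram window in frames
#'   (default 100)
#' @param peak_merge_distance histogram peak merge threshold in bins
#'   (default 30)
#' @param k_min,k_max clamps on the adapted per-pixel component count
#' @param default_alpha learning rate outside the ROI and during warmup
#' @param T background proportion threshold
#' @param match_multiplier sigma multiplier of the match rule
#' @param k_init initial components per pixel
#' @param adapt_lr enable SSIM-scheduled learning rate inside the ROI
#' @param adapt_k enable histogram-driven component counts (2 outside the
#'   ROI); with both switches off the run is identical to
#'   [background_subtract()]
#' @param init_variance,replacement_weight,variance_floor,rho_mode passed to
#'   [gmm_params()]
#' @param ssim an [ssim_params()]
#' @return an `itf_config` list
#' @export
itf_config <- function(warmup_frames = 100L, roi_margin = 5L,
                       hist_window = 100L, peak_merge_distance = 30L,
                       k_min = 1L, k_max = 5L,
                       default_alpha = 0.005, T = 0.7,
                       match_multiplier = 2.5, k_init = 3L,
                       adapt_lr = TRUE, adapt_k = TRUE,
                       init_variance = 225, replacement_weight = 0.05,
                       variance_floor = 1, rho_mode = "alpha",
                       ssim = ssim_params()) {
  stopifnot(warmup_frames >= 1L, hist_window >= 1L)
  structure(as.list(environment()), class = "itf_config")
}

#' Adaptive background subtraction with image temporal features
#'
#' Two-phase driver. Phase 1 runs the plain mixture model over the warmup
#' frames and freezes the ROI around everything detected. Phase 2, per
#' frame: updates per-pixel rolling intensity histograms inside the ROI,
#' computes the global SSIM between the current and previous ROI crops, sets
#' the in-ROI learning rate by the `(1 - SSIM)/80` schedule (the model
#' default elsewhere), adapts per-pixel component counts to the surviving
#' histogram peaks (fixed at 2 outside the ROI), and then classifies and
#' updates the mixture grid.
#'
#' @param frames a frame sequence with at least `warmup_frames + 1` frames
#' @param config an [itf_config()]
#' @return an object of class `itf_gmm`: list with per-frame logical `masks`
#'   (warmup masks flagged by the `warmup` attribute), the `roi`, per-frame
#'   `ssim` and `alpha` traces, per-frame component-count summaries
#'   (`k_stats`), the final `model` and the `config`
#' @export
itf_gmm <- function(frames, config = itf_config()) {
  frames <- as_frame_sequence(frames)
  cf <- config
  n <- length(frames)
  if (n < cf$warmup_frames + 1L)
    stop("need at least warmup_frames + 1 = ", cf$warmup_frames + 1L,
         " frames, got ", n)
  params <- gmm_params(default_alpha = cf$default_alpha, T = cf$T,
                       match_multiplier = cf$match_multiplier,
                       init_variance = cf$init_variance,
                       replacement_weight = cf$replacement_weight,
                       variance_floor = cf$variance_floor,
                       rho_mode = cf$rho_mode, k_max = cf$k_max)
  model <- gmm_background(frames[[1L]], k_init = cf$k_init, params = params)
  h <- model$height; w <- model$width
  masks <- vector("list", n)
  ssim_trace <- rep(NA_real_, n)
  alpha_trace <- rep(NA_real_, n)
  k_stats <- matrix(NA_real_, n, 3L,
                    dimnames = list(NULL, c("min", "median", "max")))
  masks[[1L]] <- matrix(FALSE, h, w)
  warm <- seq_len(min(cf$warmup_frames, n))
  for (t in warm[-1L])
    masks[[t]] <- step_frame(model, frames[[t]], alpha = cf$default_alpha)
  roi <- build_roi(masks[warm], margin = cf$roi_margin)
  use_itf <- cf$adapt_lr || cf$adapt_k
  if (use_itf) {
    rpix <- roi_pixel_index(roi, h)
    nroi <- length(rpix)
    counts <- matrix(0L, nroi, 256L)
    ring <- matrix(0L, nroi, cf$hist_window)
    nseen <- 0L
    push <- function(frame) {
      vals <- quantize_gray(frame, rpix)
      hist_push_cpp(counts, ring, nseen %% cf$hist_window, nseen, vals)
      nseen <<- nseen + 1L
    }
    if (cf$adapt_k) {
      hist_seed <- tail(warm, cf$hist_window)
      for (t in hist_seed) push(frames[[t]])
      # outside the ROI the scene is stable: two components per pixel
      out_pix <- setdiff(seq_len(h * w), rpix)
      if (length(out_pix))
        set_component_count(model, rep(2L, length(out_pix)), pixels = out_pix)
    }
  }
  for (t in seq.int(cf$warmup_frames + 1L, n)) {
    alpha <- cf$default_alpha
    if (use_itf) {
      crop_prev <- roi_crop(gray_plane(frames[[t - 1L]]), roi)
      crop_cur <- roi_crop(gray_plane(frames[[t]]), roi)
      ssim_trace[t] <- global_ssim(crop_prev, crop_cur, cf$ssim)
      if (cf$adapt_lr) {
        alpha_roi <- learning_rate_from_ssim(ssim_trace[t])
        alpha <- matrix(cf$default_alpha, h, w)
        alpha[roi$rows[1L]:(roi$rows[2L] - 1L),
              roi$cols[1L]:(roi$cols[2L] - 1L)] <- alpha_roi
        alpha_trace[t] <- alpha_roi
      }
      if (cf$adapt_k) {
        push(frames[[t]])
        praw <- count_peaks_grid_cpp(counts, cf$peak_merge_distance)
        targets <- pmin(pmax(praw, cf$k_min), cf$k_max)
        chg <- which(targets != model$kcount[rpix])
        if (length(chg)) {
          grow <- chg[targets[chg] > model$kcount[rpix][chg]]
          seeds <- rep(0, length(targets))
          if (length(grow)) {
            px <- gray_plane(frames[[t]])
            for (g in grow) {
              pk <- peaks_cpp(counts[g, ], cf$peak_merge_distance)
              mix <- mixture_at(model, ((rpix[g] - 1L) %% h) + 1L,
                                ((rpix[g] - 1L) %/% h) + 1L)
              seeds[g] <- least_covered_peak(pk, mix$means, mix$vars,
                                             px[rpix[g]])
            }
          }
          set_component_count(model, targets[chg], seeds = seeds[chg],
                              pixels = rpix[chg])
        }
      }
    }
    masks[[t]] <- step_frame(model, frames[[t]], alpha = alpha)
    k_stats[t, ] <- c(min(model$kcount), stats::median(model$kcount),
                      max(model$kcount))
  }
  attr(masks, "warmup") <- warm
  structure(list(masks = masks, roi = roi, warmup = warm,
                 ssim = ssim_trace, alpha = alpha_trace, k_stats = k_stats,
                 model = model, config = cf),
            class = "itf_gmm")
}

#' @export
print.itf_gmm <- function(x, ...) {
  post <- x$ssim[!is.na(x$ssim)]
  cat(sprintf("<itf_gmm> %d frames (%d warmup), ROI rows [%d,%d) cols [%d,%d)\n",
              length(x$masks), length(x$warmup),
              x$roi$rows[1L], x$roi$rows[2L], x$roi$cols[1L], x$roi$cols[2L]))
  if (length(post))
    cat(sprintf("  SSIM: mean %.4f [%.4f, %.4f]; lr features: lr=%s k=%s\n",
                mean(post), min(post), max(post),
                x$config$adapt_lr, x$config$adapt_k))
  invisible(x)
}

gray_plane <- function(frame) {
  d <- frame_shape(frame)
  if (d[3L] == 1L) {
    if (length(dim(frame)) == 3L) dim(frame) <- d[1:2]
    frame
  } else {
    (frame[, , 1L] + frame[, , 2L] + frame[, , 3L]) / 3
  }
}

quantize_gray <- function(frame, pixels) {
  g <- gray_plane(frame)
  as.integer(pmin(pmax(round(g[pixels]), 0), 255))
}
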