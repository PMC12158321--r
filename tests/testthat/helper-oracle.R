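# Straight-line scalar reference implementation of the per-pixel mixture
# background model, independent of the package's grid code. Operates on one
# pixel's intensity history and returns the foreground flag per frame.
#
# Conventions mirrored deliberately: equal initial weights 1/K with the first
# mean at the first value and the rest at 0; background prefix B computed
# from the previous frame's sorted weights before any update; first matching
# component in sort order within mult*sigma; matched component updated with
# rate alpha (weights) and rho = alpha (mean/variance, against the
# pre-update mean); unmatched weights decay; on no-match the last-ranked
# component is replaced; weights renormalized; stable re-sort by w/v
# descending; variance floored.
oracle_pixel_gmm <- function(history, k_init = 3, alpha = 0.005, T = 0.7,
                             mult = 2.5, var0 = 225, w0 = 0.05, floor_v = 1) {
  K <- k_init
  w <- rep(1 / K, K)
  mu <- c(history[1], rep(0, K - 1))
  v <- rep(var0, K)
  fg <- logical(length(history))
  fg[1] <- FALSE
  for (t in seq_along(history)[-1]) {
    x <- history[t]
    cw <- cumsum(w)
    B <- which(cw >= T - 1e-12)[1]
    if (is.na(B)) B <- K
    m <- NA_integer_
    for (i in seq_len(K)) {
      if (abs(x - mu[i]) <= mult * sqrt(v[i])) { m <- i; break }
    }
    fg[t] <- is.na(m) || m > B
    if (alpha > 0) {
      if (!is.na(m)) {
        d2 <- (x - mu[m])^2
        w <- (1 - alpha) * w
        w[m] <- w[m] + alpha
        mu[m] <- mu[m] + alpha * (x - mu[m])
        v[m] <- max((1 - alpha) * v[m] + alpha * d2, floor_v)
      } else {
        w <- (1 - alpha) * w
        w[K] <- w0
        mu[K] <- x
        v[K] <- max(var0, floor_v)
      }
      w <- w / sum(w)
      ord <- order(-(w / v))  # stable for ties
      w <- w[ord]; mu <- mu[ord]; v <- v[ord]
    }
  }
  fg
}

# run the package's grid model over a 1-pixel video built from a history
grid_pixel_gmm <- function(history, k_init = 3, params = gmm_params()) {
  model <- gmm_background(matrix(history[1], 1, 1), k_init = k_init,
                          params = params)
  fg <- logical(length(history))
  for (t in seq_along(history)[-1])
    fg[t] <- step_frame(model, matrix(history[t], 1, 1))[1, 1]
  fg
}

# small deterministic scene for pipeline-level tests
tiny_scene <- function(seed = 5, n_frames = 30L) {
  generate_sequence(synthetic_scene_config(
    height = 40L, width = 48L, n_frames = n_frames, n_targets = 1L,
    target_area = c(25, 40), dwell_prob = 0.3, noise_sd = 2, seed = seed))
}
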