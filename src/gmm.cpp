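#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-pixel Gaussian mixture background model, grid form.
//
// State layout (one row per pixel, components sorted by w/v descending):
//   w  : n x kmax weights
//   mu : n x (kmax*nch) means, column block (k-1)*nch + c for component k,
//        channel c
//   v  : n x kmax shared-across-channel variances
//   k  : active component count per pixel
// All state matrices are modified in place.

static inline void stable_sort_pixel(NumericMatrix &w, NumericMatrix &mu,
                                     NumericMatrix &v, int p, int K, int nch) {
  // insertion sort on key = w/v descending; stable (equal keys keep order)
  for (int i = 1; i < K; ++i) {
    double wi = w(p, i), vi = v(p, i);
    double key = wi / vi;
    std::vector<double> mui(nch);
    for (int c = 0; c < nch; ++c) mui[c] = mu(p, i * nch + c);
    int j = i - 1;
    while (j >= 0 && (w(p, j) / v(p, j)) < key) {
      w(p, j + 1) = w(p, j);
      v(p, j + 1) = v(p, j);
      for (int c = 0; c < nch; ++c) mu(p, (j + 1) * nch + c) = mu(p, j * nch + c);
      --j;
    }
    w(p, j + 1) = wi;
    v(p, j + 1) = vi;
    for (int c = 0; c < nch; ++c) mu(p, (j + 1) * nch + c) = mui[c];
  }
}

static inline void normalize_pixel(NumericMatrix &w, int p, int K) {
  double s = 0.0;
  for (int i = 0; i < K; ++i) s += w(p, i);
  if (s > 0) for (int i = 0; i < K; ++i) w(p, i) /= s;
  else for (int i = 0; i < K; ++i) w(p, i) = 1.0 / K;
}

// [[Rcpp::export]]
IntegerVector gmm_step_cpp(NumericMatrix w, NumericMatrix mu, NumericMatrix v,
                           IntegerVector kvec, NumericMatrix frame,
                           NumericVector alpha, double T, double mult,
                           double var0, double w0, double var_floor,
                           int rho_mode, bool update) {
  const int n = w.nrow();
  const int nch = frame.ncol();
  const bool avec = alpha.size() > 1;
  IntegerVector mask(n);
  for (int p = 0; p < n; ++p) {
    const int K = kvec[p];
    // background prefix from current (sorted) weights
    double cum = 0.0; int B = K;
    for (int b = 0; b < K; ++b) {
      cum += w(p, b);
      if (cum >= T - 1e-12) { B = b + 1; break; }
    }
    // first matching component in rank order (all channels within mult*sigma)
    int m = -1;
    for (int i = 0; i < K && m < 0; ++i) {
      const double s = std::sqrt(v(p, i));
      bool ok = true;
      for (int c = 0; c < nch; ++c) {
        if (std::fabs(frame(p, c) - mu(p, i * nch + c)) > mult * s) { ok = false; break; }
      }
      if (ok) m = i;
    }
    mask[p] = (m < 0) ? 1 : ((m < B) ? 0 : 1);
    if (!update) continue;
    const double a = avec ? alpha[p] : alpha[0];
    if (a <= 0.0) continue;  // alpha = 0 freezes this pixel entirely
    if (m >= 0) {
      double d2 = 0.0;
      for (int c = 0; c < nch; ++c) {
        const double dd = frame(p, c) - mu(p, m * nch + c);
        d2 += dd * dd;
      }
      double rho = a;
      if (rho_mode == 1) {
        const double vv = v(p, m);
        const double eta = std::pow(2.0 * M_PI * vv, -0.5 * nch) *
                           std::exp(-0.5 * d2 / vv);
        rho = a * eta;
        if (rho > 1.0) rho = 1.0;
      }
      for (int i = 0; i < K; ++i)
        w(p, i) = (1.0 - a) * w(p, i) + (i == m ? a : 0.0);
      for (int c = 0; c < nch; ++c)
        mu(p, m * nch + c) += rho * (frame(p, c) - mu(p, m * nch + c));
      v(p, m) = (1.0 - rho) * v(p, m) + rho * d2;
      if (v(p, m) < var_floor) v(p, m) = var_floor;
    } else {
      for (int i = 0; i < K; ++i) w(p, i) *= (1.0 - a);
      const int r = K - 1;  // lowest-ranked component is replaced
      w(p, r) = w0;
      v(p, r) = var0 > var_floor ? var0 : var_floor;
      for (int c = 0; c < nch; ++c) mu(p, r * nch + c) = frame(p, c);
    }
    normalize_pixel(w, p, K);
    stable_sort_pixel(w, mu, v, p, K, nch);
  }
  return mask;
}

// [[Rcpp::export]]
void gmm_normalize_sort_cpp(NumericMatrix w, NumericMatrix mu, NumericMatrix v,
                            IntegerVector kvec, IntegerVector pixels, int nch) {
  for (int j = 0; j < pixels.size(); ++j) {
    const int p = pixels[j] - 1;
    normalize_pixel(w, p, kvec[p]);
    stable_sort_pixel(w, mu, v, p, kvec[p], nch);
  }
}

// rolling per-pixel temporal histograms: push one frame of quantized values
// [[Rcpp::export]]
void hist_push_cpp(IntegerMatrix counts, IntegerMatrix ring, int pos,
                   int nseen, IntegerVector values) {
  const int n = counts.nrow();
  const int W = ring.ncol();
  for (int p = 0; p < n; ++p) {
    if (nseen >= W) {
      const int old = ring(p, pos);
      counts(p, old) -= 1;
    }
    const int val = values[p];
    ring(p, pos) = val;
    counts(p, val) += 1;
  }
}

// surviving peak bins (0-based) of one 256-bin histogram: local maxima with
// plateaus collapsed to their first bin, then greedy left-to-right merging of
// maxima closer than merge_dist, keeping the taller (ties keep the left one)
static std::vector<int> peaks_one(const int *h, int nbins, int merge_dist) {
  std::vector<int> peaks;
  int i = 0;
  while (i < nbins) {
    int j = i;
    while (j + 1 < nbins && h[j + 1] == h[i]) ++j;  // plateau [i, j]
    const bool left_ok = (i == 0) || (h[i - 1] < h[i]);
    const bool right_ok = (j == nbins - 1) || (h[j + 1] < h[i]);
    if (h[i] > 0 && left_ok && right_ok) peaks.push_back(i);
    i = j + 1;
  }
  if (peaks.size() < 2 || merge_dist <= 1) return peaks;
  std::vector<int> kept;
  kept.push_back(peaks[0]);
  for (size_t t = 1; t < peaks.size(); ++t) {
    const int p = peaks[t];
    const int q = kept.back();
    if (p - q < merge_dist) {
      if (h[p] > h[q]) kept.back() = p;
    } else {
      kept.push_back(p);
    }
  }
  return kept;
}

// [[Rcpp::export]]
IntegerVector peaks_cpp(IntegerVector h, int merge_dist) {
  std::vector<int> out = peaks_one(h.begin(), h.size(), merge_dist);
  return wrap(out);
}

// [[Rcpp::export]]
IntegerVector count_peaks_grid_cpp(IntegerMatrix counts, int merge_dist) {
  const int n = counts.nrow(), nb = counts.ncol();
  IntegerVector out(n);
  std::vector<int> h(nb);
  for (int p = 0; p < n; ++p) {
    for (int b = 0; b < nb; ++b) h[b] = counts(p, b);
    out[p] = (int) peaks_one(h.data(), nb, merge_dist).size();
  }
  return out;
}

// ---- convolution gather/scatter helpers (feature maps are C x N, N spatial
// column-major; idx maps output positions to padded positions, pm maps padded
// positions to source positions) ----

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix x, IntegerMatrix idx, IntegerVector pm) {
  const int C = x.nrow();
  const int nout = idx.nrow();
  const int k2 = idx.ncol();
  NumericMatrix col(C * k2, nout);
  const double *xp = x.begin();
  double *cp = col.begin();
  const int *ip = idx.begin();
  const int *pp = pm.begin();
  for (int n = 0; n < nout; ++n) {
    double *cd = cp + (R_xlen_t) n * C * k2;
    for (int o = 0; o < k2; ++o) {
      const int src = pp[ip[(R_xlen_t) o * nout + n] - 1] - 1;
      const double *xs = xp + (R_xlen_t) src * C;
      for (int c = 0; c < C; ++c) cd[o * C + c] = xs[c];
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix dcol, IntegerMatrix idx,
                         IntegerVector pm, int C, int N) {
  const int nout = idx.nrow();
  const int k2 = idx.ncol();
  NumericMatrix dx(C, N);
  double *xp = dx.begin();
  const double *cp = dcol.begin();
  const int *ip = idx.begin();
  const int *pp = pm.begin();
  for (int n = 0; n < nout; ++n) {
    const double *cd = cp + (R_xlen_t) n * C * k2;
    for (int o = 0; o < k2; ++o) {
      const int src = pp[ip[(R_xlen_t) o * nout + n] - 1] - 1;
      double *xd = xp + (R_xlen_t) src * C;
      for (int c = 0; c < C; ++c) xd[c] += cd[o * C + c];
    }
  }
  return dx;
}
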