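#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Plug-in generalized transfer entropy over all ordered pairs of a binary
// neurons x bins matrix. State coding: predicted bit y_{t+1}, target history
// (y_t, ..., y_{t-k+1}), source window (x_{t+1}, ..., x_{t-k+2}) when
// instant feedback is on, else (x_t, ..., x_{t-k+1}). Probabilities are raw
// histogram frequencies pooled over all valid t.
// [[Rcpp::export]]
NumericMatrix gte_matrix_cpp(IntegerMatrix bins, int k, bool instant) {
  const int n = bins.nrow();
  const int T = bins.ncol();
  const int shift = instant ? 1 : 0;
  const int ny = 1 << k; // target-history states
  const int nx = 1 << k; // source-window states (shifted, same length)
  const int nstates = 2 * ny * nx;
  const int t0 = k - 1;            // 0-based; y history reaches t-k+1 >= 0
  const int t1 = T - 2;            // y_{t+1} and x_{t+1} must exist
  const int nt = t1 - t0 + 1;
  if (nt < 1) stop("series too short for the requested Markov order");

  // per-neuron codes at each valid t
  std::vector<int> ycode((size_t)n * nt), xcode((size_t)n * nt),
      ynext((size_t)n * nt);
  for (int i = 0; i < n; ++i) {
    for (int t = t0; t <= t1; ++t) {
      int yc = 0, xc = 0;
      for (int j = 0; j < k; ++j) yc |= bins(i, t - j) << j;
      for (int j = 0; j < k; ++j) xc |= bins(i, t + shift - j) << j;
      const size_t at = (size_t)i * nt + (t - t0);
      ycode[at] = yc;
      xcode[at] = xc;
      ynext[at] = bins(i, t + 1);
    }
  }

  NumericMatrix te(n, n);
  std::vector<int> cnt(nstates), c_yx(ny * nx), c_yny(2 * ny), c_yh(ny);
  const double log2e = 1.0 / std::log(2.0);
  for (int j = 0; j < n; ++j) { // target
    // target-only marginals are shared across sources
    std::fill(c_yny.begin(), c_yny.end(), 0);
    std::fill(c_yh.begin(), c_yh.end(), 0);
    const size_t tj = (size_t)j * nt;
    for (int t = 0; t < nt; ++t) {
      const int yh = ycode[tj + t];
      ++c_yny[ynext[tj + t] + 2 * yh];
      ++c_yh[yh];
    }
    for (int i = 0; i < n; ++i) { // source
      if (i == j) continue;
      std::fill(cnt.begin(), cnt.end(), 0);
      std::fill(c_yx.begin(), c_yx.end(), 0);
      const size_t ti = (size_t)i * nt;
      for (int t = 0; t < nt; ++t) {
        const int state =
            ynext[tj + t] + 2 * (ycode[tj + t] + ny * xcode[ti + t]);
        ++cnt[state];
      }
      for (int s = 0; s < nstates; ++s) c_yx[s >> 1] += cnt[s];
      double acc = 0.0;
      for (int s = 0; s < nstates; ++s) {
        const int c = cnt[s];
        if (c == 0) continue;
        const int yn = s & 1;
        const int yh = (s >> 1) & (ny - 1);
        const double p_full = (double)c / c_yx[s >> 1];
        const double p_red = (double)c_yny[yn + 2 * yh] / c_yh[yh];
        acc += c * std::log(p_full / p_red);
      }
      te(i, j) = acc * log2e / nt;
    }
  }
  return te;
}

// Two-threshold hysteresis sweep: an event opens at the first value >= hi,
// closes when the value drops below lo; events shorter than min_frames are
// discarded. Returns 1-based opening indices.
// [[Rcpp::export]]
IntegerVector schmitt_onsets_cpp(NumericVector x, double hi, double lo,
                                 int min_frames) {
  std::vector<int> onsets;
  bool open = false;
  int start = 0;
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    if (!open) {
      if (x[i] >= hi) {
        open = true;
        start = i;
      }
    } else if (x[i] < lo) {
      if (i - start >= min_frames) onsets.push_back(start + 1);
      open = false;
    }
  }
  if (open && n - start >= min_frames) onsets.push_back(start + 1);
  return wrap(onsets);
}
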