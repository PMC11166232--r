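#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fluctuation (F) and distribution (D) measures for a batch of windows.
// `win` holds one window per column (m rows). Both measures are normalized
// to [0,1] against the scale range [smin, smax].
//
// F sums, over maximal monotone segments of the window, the absolute change
// across the segment divided by its length in steps, normalized by the
// largest possible value (full-range alternation every step). Plateaus
// (equal consecutive values) extend the current segment rather than opening
// a new one.
//
// D sorts the window and compares empirical pairwise gaps with the gaps of
// an ideal equidistant spread across the scale; only deficits (empirical
// gap smaller than ideal) count.
// [[Rcpp::export]]
NumericMatrix dc_fd_windows(NumericMatrix win, double smin, double smax) {
  const int m = win.nrow(), k = win.ncol();
  if (m < 3) stop("window length must be >= 3");
  if (!(smax > smin)) stop("scale_max must exceed scale_min");
  const double range = smax - smin;
  const double denomF = range * (m - 1);
  const double d = range / (m - 1);
  double denomD = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) denomD += (j - i) * d;

  NumericMatrix out(2, k);
  std::vector<double> y(m);
  for (int c = 0; c < k; ++c) {
    // fluctuation: walk the diffs, closing a segment at direction reversals
    double F = 0.0;
    int segStart = 0, dir = 0;
    for (int t = 1; t < m; ++t) {
      const double diff = win(t, c) - win(t - 1, c);
      const int s = (diff > 0) - (diff < 0);
      if (s != 0 && dir != 0 && s != dir) {
        F += std::fabs(win(t - 1, c) - win(segStart, c)) / (t - 1 - segStart);
        segStart = t - 1;
        dir = s;
      } else if (s != 0 && dir == 0) {
        dir = s;
      }
    }
    if (m - 1 > segStart)
      F += std::fabs(win(m - 1, c) - win(segStart, c)) / (m - 1 - segStart);
    F /= denomF;

    // distribution: deficit of sorted pairwise gaps vs ideal spacing
    for (int t = 0; t < m; ++t) y[t] = win(t, c);
    std::sort(y.begin(), y.end());
    double deficit = 0.0;
    for (int i = 0; i < m; ++i) {
      for (int j = i + 1; j < m; ++j) {
        const double gap = y[j] - y[i];
        const double ideal = (j - i) * d;
        if (ideal > gap) deficit += ideal - gap;
      }
    }
    out(0, c) = F;
    out(1, c) = 1.0 - deficit / denomD;
  }
  return out;
}
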