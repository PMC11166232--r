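#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-split change-point scanners. All three report the first day of the
// new regime (1-based), the cost reduction of the best two-segment fit over
// the one-segment fit ("score"), and the one-segment baseline cost. Ties are
// broken to the earliest admissible day.

static inline double seg_sse(const std::vector<double>& s,
                             const std::vector<double>& s2, int a, int b) {
  // SSE around the segment mean on the half-open index range [a, b)
  const int len = b - a;
  const double su = s[b] - s[a];
  const double sse = (s2[b] - s2[a]) - su * su / len;
  return sse > 0.0 ? sse : 0.0;
}

// [[Rcpp::export]]
List cp_scan_mean_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 4) stop("need at least 4 points");
  std::vector<double> s(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s[i + 1] = s[i] + x[i];
    s2[i + 1] = s2[i] + x[i] * x[i];
  }
  const double base = seg_sse(s, s2, 0, n);
  double best = R_PosInf;
  int bestk = 2;
  for (int k = 2; k <= n; ++k) {  // segments [1..k-1], [k..n]
    const double c = seg_sse(s, s2, 0, k - 1) + seg_sse(s, s2, k - 1, n);
    if (!R_FINITE(best) || c < best - 1e-12 * (1.0 + std::fabs(best))) {
      best = c;
      bestk = k;
    }
  }
  double score = base - best;
  if (score < 0.0) score = 0.0;
  return List::create(_["day"] = bestk, _["score"] = score,
                      _["baseline"] = base);
}

// [[Rcpp::export]]
List cp_scan_variance_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 6) stop("need at least 6 points");
  const double delta = 1e-9;  // guard against log(0) on constant segments
  std::vector<double> s(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s[i + 1] = s[i] + x[i];
    s2[i + 1] = s2[i] + x[i] * x[i];
  }
  const double base = n * std::log(seg_sse(s, s2, 0, n) / n + delta);
  double best = R_PosInf;
  int bestk = 3;
  for (int k = 3; k <= n - 1; ++k) {  // each segment needs >= 2 points
    const int l1 = k - 1, l2 = n - k + 1;
    const double c = l1 * std::log(seg_sse(s, s2, 0, k - 1) / l1 + delta) +
                     l2 * std::log(seg_sse(s, s2, k - 1, n) / l2 + delta);
    if (!R_FINITE(best) || c < best - 1e-12 * (1.0 + std::fabs(best))) {
      best = c;
      bestk = k;
    }
  }
  double score = base - best;
  if (score < 0.0) score = 0.0;
  return List::create(_["day"] = bestk, _["score"] = score,
                      _["baseline"] = base);
}

static inline double seg_sse_line(const std::vector<double>& sy,
                                  const std::vector<double>& sy2,
                                  const std::vector<double>& sty, int a,
                                  int b) {
  // SSE of an OLS line on days a+1..b (1-based), half-open range [a, b)
  const int len = b - a;
  if (len <= 2) return 0.0;
  const double ta = a + 1.0, tb = (double)b;
  const double St = (tb * (tb + 1.0) - (ta - 1.0) * ta) / 2.0;
  const double Stt =
      (tb * (tb + 1.0) * (2.0 * tb + 1.0) - (ta - 1.0) * ta * (2.0 * ta - 1.0)) /
      6.0;
  const double Sy = sy[b] - sy[a];
  const double Syy = sy2[b] - sy2[a];
  const double Sty = sty[b] - sty[a];
  const double Sxx = Stt - St * St / len;
  const double Sxy = Sty - St * Sy / len;
  double Syyc = Syy - Sy * Sy / len;
  if (Syyc < 0.0) Syyc = 0.0;
  if (Sxx <= 0.0) return Syyc;
  double sse = Syyc - Sxy * Sxy / Sxx;
  return sse > 0.0 ? sse : 0.0;
}

// [[Rcpp::export]]
List cp_scan_trend_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 6) stop("need at least 6 points");
  std::vector<double> sy(n + 1, 0.0), sy2(n + 1, 0.0), sty(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    sy[i + 1] = sy[i] + x[i];
    sy2[i + 1] = sy2[i] + x[i] * x[i];
    sty[i + 1] = sty[i] + (i + 1.0) * x[i];
  }
  const double base = seg_sse_line(sy, sy2, sty, 0, n);
  double best = R_PosInf;
  int bestk = 3;
  for (int k = 3; k <= n - 1; ++k) {
    const double c = seg_sse_line(sy, sy2, sty, 0, k - 1) +
                     seg_sse_line(sy, sy2, sty, k - 1, n);
    if (!R_FINITE(best) || c < best - 1e-12 * (1.0 + std::fabs(best))) {
      best = c;
      bestk = k;
    }
  }
  double score = base - best;
  if (score < 0.0) score = 0.0;
  return List::create(_["day"] = bestk, _["score"] = score,
                      _["baseline"] = base);
}
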