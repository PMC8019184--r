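#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Streaming Pearson correlation between the breeding and non-breeding
// pairwise Euclidean distances of a paired population. The n(n-1)/2 pairs
// are accumulated on the fly (long double sums), so no distance matrix is
// ever materialised; the N = 10,000 whole-population score needs O(n)
// memory.
// [[Rcpp::export]]
List pair_distance_correlation_cpp(NumericVector bx, NumericVector by,
                                   NumericVector wx, NumericVector wy) {
  const R_xlen_t n = bx.size();
  if (by.size() != n || wx.size() != n || wy.size() != n)
    stop("coordinate vectors must have equal length");
  long double s1 = 0, s2 = 0, s11 = 0, s22 = 0, s12 = 0;
  const double *pbx = bx.begin(), *pby = by.begin();
  const double *pwx = wx.begin(), *pwy = wy.begin();
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    const double bxi = pbx[i], byi = pby[i], wxi = pwx[i], wyi = pwy[i];
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double dx1 = bxi - pbx[j], dy1 = byi - pby[j];
      const double dx2 = wxi - pwx[j], dy2 = wyi - pwy[j];
      const double d1 = std::sqrt(dx1 * dx1 + dy1 * dy1);
      const double d2 = std::sqrt(dx2 * dx2 + dy2 * dy2);
      s1 += d1; s2 += d2;
      s11 += d1 * d1; s22 += d2 * d2; s12 += d1 * d2;
    }
  }
  const long double cnt = (long double)n * (n - 1) / 2;
  const long double v1 = s11 - s1 * s1 / cnt;
  const long double v2 = s22 - s2 * s2 / cnt;
  double r = NA_REAL;
  bool degenerate = (v1 <= 0 || v2 <= 0);
  if (!degenerate)
    r = (double)((s12 - s1 * s2 / cnt) / std::sqrt(v1 * v2));
  return List::create(_["r"] = r, _["degenerate"] = degenerate);
}
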