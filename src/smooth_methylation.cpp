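#include <Rcpp.h>
using namespace Rcpp;

// Coverage-weighted local-linear smoothing of per-CpG methylation ratios.
//
// For each CpG i the window is the wider of `bandwidth` bp centred on the
// CpG and the span of the `min_cpg_window` nearest CpGs. Within the window a
// weighted linear fit of ratio on position is evaluated at the CpG, with
// weights = tricube(distance / half-width) * coverage. Positions must be
// sorted ascending. CpGs whose window carries zero total weight yield NaN.
//
// [[Rcpp::export]]
NumericVector smooth_llin(NumericVector pos, NumericVector ratio,
                          NumericVector cov, double bandwidth,
                          int min_cpg_window) {
  int n = pos.size();
  NumericVector out(n);
  if (n == 0) return out;

  for (int i = 0; i < n; ++i) {
    double half = bandwidth / 2.0;
    // expand window to include at least min_cpg_window CpGs (k nearest)
    int lo = i, hi = i;
    while (hi - lo + 1 < min_cpg_window && (lo > 0 || hi < n - 1)) {
      double dlo = (lo > 0) ? pos[i] - pos[lo - 1] : R_PosInf;
      double dhi = (hi < n - 1) ? pos[hi + 1] - pos[i] : R_PosInf;
      if (dlo <= dhi) --lo; else ++hi;
    }
    double span = std::max(pos[i] - pos[lo], pos[hi] - pos[i]);
    if (span > half) half = span;
    // include every CpG within half
    while (lo > 0 && pos[i] - pos[lo - 1] <= half) --lo;
    while (hi < n - 1 && pos[hi + 1] - pos[i] <= half) ++hi;

    // weighted linear fit of ratio ~ (pos - pos[i])
    double sw = 0, swx = 0, swy = 0, swxx = 0, swxy = 0;
    for (int j = lo; j <= hi; ++j) {
      if (cov[j] <= 0 || !R_finite(ratio[j])) continue;
      double d = std::fabs(pos[j] - pos[i]) / (half + 1e-9);
      double u = 1.0 - d * d * d;
      double w = (u > 0 ? u * u * u : 0.0) * cov[j];
      if (w <= 0) continue;
      double x = pos[j] - pos[i];
      sw += w; swx += w * x; swy += w * ratio[j];
      swxx += w * x * x; swxy += w * x * ratio[j];
    }
    if (sw <= 0) { out[i] = NA_REAL; continue; }
    double det = sw * swxx - swx * swx;
    double fit;
    if (det > 1e-8 * sw * swxx && swxx > 0) {
      double b = (sw * swxy - swx * swy) / det;
      double a = (swy - b * swx) / sw;
      fit = a;  // evaluated at x = 0
    } else {
      fit = swy / sw;  // degenerate design: weighted mean
    }
    if (fit < 0) fit = 0;
    if (fit > 1) fit = 1;
    out[i] = fit;
  }
  return out;
}
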