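#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Moving-window lagged partial correlation between a soil-moisture anomaly
// series and a VPD anomaly series on a shared daily axis.
//
// For each focal day d the window covers the `window` consecutive days
// t in [d - floor(window/2), d + window - floor(window/2) - 1] (truncated at
// the series edges).  Each window day t contributes the triple
// (sm[t - lag], vpd[t], vpd[t - lag]); triples with any missing member are
// dropped.  The statistic is the first-order partial correlation
//   (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))
// with x = lagged SM, y = VPD, z = lagged VPD.  Windows with fewer than
// `min_pairs` valid triples, a zero-variance member, or a degenerate
// denominator yield NA.
// [[Rcpp::export]]
List rolling_pcor_cpp(NumericVector sm, NumericVector vpd,
                      int lag, int window, int min_pairs) {
  const int n = sm.size();
  if (vpd.size() != n) stop("sm and vpd must share one date axis");
  if (lag < 0) stop("lag must be non-negative");
  if (window < 2) stop("window must span at least 2 days");

  NumericVector pcor(n, NA_REAL);
  IntegerVector npairs(n);
  const int lo_off = -(window / 2);

  for (int d = 0; d < n; ++d) {
    int t0 = d + lo_off;
    int t1 = t0 + window - 1;
    if (t0 < lag) t0 = lag;  // triples need t - lag >= 0
    if (t1 > n - 1) t1 = n - 1;

    double sx = 0, sy = 0, sz = 0, sxx = 0, syy = 0, szz = 0,
           sxy = 0, sxz = 0, syz = 0;
    int m = 0;
    for (int t = t0; t <= t1; ++t) {
      const double x = sm[t - lag], y = vpd[t], z = vpd[t - lag];
      if (ISNAN(x) || ISNAN(y) || ISNAN(z)) continue;
      sx += x; sy += y; sz += z;
      sxx += x * x; syy += y * y; szz += z * z;
      sxy += x * y; sxz += x * z; syz += y * z;
      ++m;
    }
    npairs[d] = m;
    if (m < min_pairs) continue;

    const double vx = sxx - sx * sx / m;
    const double vy = syy - sy * sy / m;
    const double vz = szz - sz * sz / m;
    if (vx <= 0 || vy <= 0 || vz <= 0) continue;  // constant member

    const double rxy = (sxy - sx * sy / m) / std::sqrt(vx * vy);
    const double rxz = (sxz - sx * sz / m) / std::sqrt(vx * vz);
    const double ryz = (syz - sy * sz / m) / std::sqrt(vy * vz);
    const double den = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
    if (den <= 1e-12) continue;  // a control correlation is +-1

    double pc = (rxy - rxz * ryz) / std::sqrt(den);
    if (pc > 1.0) pc = 1.0;
    if (pc < -1.0) pc = -1.0;
    pcor[d] = pc;
  }
  return List::create(_["pcor"] = pcor, _["n_pairs"] = npairs);
}
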