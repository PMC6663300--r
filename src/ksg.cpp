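#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Max-norm distance between rows i and j over columns [c0, c0+nc).
static inline double maxdist(const NumericMatrix& d, int i, int j, int c0, int nc) {
  double m = 0.0;
  for (int c = c0; c < c0 + nc; ++c) {
    double v = std::fabs(d(i, c) - d(j, c));
    if (v > m) m = v;
  }
  return m;
}

// Kraskov algorithm-1 / Frenzel-Pompe CMI estimator.
// dat holds columns [X (dx) | Y (dy) | Z (dz)]; brute-force O(M^2) search.
// Counts use strict inequality on the k-th neighbour radius, per the
// algorithm-1 convention.
// [[Rcpp::export]]
double ksg_cmi_cpp(NumericMatrix dat, int dx, int dy, int dz, int k) {
  const int m = dat.nrow();
  const int d = dx + dy + dz;
  std::vector<double> jd(m);
  double acc = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j)
      jd[j] = (j == i) ? R_PosInf : maxdist(dat, i, j, 0, d);
    std::nth_element(jd.begin(), jd.begin() + (k - 1), jd.end());
    const double eps = jd[k - 1];  // k-th smallest joint distance
    int nxz = 0, nyz = 0, nz = 0;
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      double dzv = dz > 0 ? maxdist(dat, i, j, dx + dy, dz) : 0.0;
      if (dzv >= eps) continue;  // z-distance bounds both marginal distances
      if (dz > 0) ++nz;
      double dxv = maxdist(dat, i, j, 0, dx);
      if (std::max(dxv, dzv) < eps) ++nxz;
      double dyv = maxdist(dat, i, j, dx, dy);
      if (std::max(dyv, dzv) < eps) ++nyz;
    }
    if (dz > 0)
      acc += R::digamma(nz + 1.0) - R::digamma(nxz + 1.0) - R::digamma(nyz + 1.0);
    else
      acc += -R::digamma(nxz + 1.0) - R::digamma(nyz + 1.0);
  }
  double val = R::digamma((double)k) + acc / m;
  if (dz == 0) val += R::digamma((double)m);
  return val;
}
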