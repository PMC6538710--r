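#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher (2012). `step` is the physical spacing
// between adjacent samples, so distances come out in physical units.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double step) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n, 0);
  std::vector<double> z(n + 1);
  int k = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".dist_transform_cpp")]]
NumericMatrix dist_transform_cpp(LogicalMatrix mask, double row_spacing,
                                 double col_spacing) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // large finite sentinel: infinities break the parabola intersections
  const double BIG = 1e30;
  NumericMatrix out(nr, nc);

  // pass 1: columns (axial)
  std::vector<double> f(nr), d(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : BIG;
    dt1d(f, d, row_spacing);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // pass 2: rows (lateral)
  std::vector<double> fr(nc), dr(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) fr[j] = out(i, j);
    dt1d(fr, dr, col_spacing);
    for (int j = 0; j < nc; ++j) out(i, j) = std::sqrt(dr[j]);
  }
  return out;
}
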