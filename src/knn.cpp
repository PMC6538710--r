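#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Leave-one-out k-NN malignancy scores for one feature subset, given the
// precomputed fold-scaled squared-difference cube.
//
// M is an n x n x m array with M[i, j, f] = (x[i,f] - x[j,f])^2 / var_f^(-i),
// the squared per-feature distance between held-out lesion i and training
// lesion j, scaled by the training-fold variance (feature dropped for a fold
// => entries 0). Distances for a subset are sums of slices; neighbours tied
// with the k-th distance (relative tolerance 1e-8) are all included and
// their labels averaged.
static void loocv_scores_from_D(const std::vector<double>& D, const int n,
                                const IntegerVector& y, const int k,
                                double* out, std::vector<double>& buf) {
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int j = 0; j < n; ++j) {
      if (j != i) buf.push_back(D[(size_t)j * n + i]);
    }
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
    double dk = buf[k - 1];
    double thr = dk + 1e-8 * std::max(dk, 1e-300);
    double s = 0.0;
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (D[(size_t)j * n + i] <= thr) {
        s += y[j];
        ++cnt;
      }
    }
    out[i] = s / cnt;
  }
}

static double auc_pairs(const double* s, const IntegerVector& y, int n) {
  double conc = 0.0;
  long npair = 0;
  for (int a = 0; a < n; ++a) {
    if (y[a] != 1) continue;
    for (int b = 0; b < n; ++b) {
      if (y[b] != 0) continue;
      ++npair;
      if (s[a] > s[b]) conc += 1.0;
      else if (s[a] == s[b]) conc += 0.5;
    }
  }
  return conc / npair;
}

//' @noRd
// [[Rcpp::export(name = ".knn_loocv_cpp")]]
NumericVector knn_loocv_cpp(NumericVector M, int n, int m, IntegerVector y,
                            int k) {
  std::vector<double> D((size_t)n * n, 0.0);
  const double* Mp = REAL(M);
  for (int f = 0; f < m; ++f) {
    const double* slice = Mp + (size_t)f * n * n;
    for (size_t t = 0; t < (size_t)n * n; ++t) D[t] += slice[t];
  }
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(n);
  loocv_scores_from_D(D, n, y, k, REAL(out), buf);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".knn_exhaustive_cpp")]]
List knn_exhaustive_cpp(NumericVector M, int n, int m, IntegerVector y, int k,
                        bool keep_scores) {
  const size_t nn = (size_t)n * n;
  const double* Mp = REAL(M);
  const unsigned long nsub = (1UL << m) - 1UL;

  std::vector<double> D(nn, 0.0);
  NumericVector auc(nsub);
  IntegerVector subset(nsub);
  NumericMatrix scores = keep_scores ? NumericMatrix(n, (int)nsub)
                                     : NumericMatrix(0, 0);
  std::vector<double> sc(n), buf;
  buf.reserve(n);

  // Gray-code walk over non-empty subsets: one feature slice added or
  // removed per step keeps the distance matrix update O(n^2).
  unsigned long prev_gray = 0UL;
  for (unsigned long t = 1; t <= nsub; ++t) {
    unsigned long gray = t ^ (t >> 1);
    unsigned long diff = gray ^ prev_gray;
    int f = 0;
    while (!((diff >> f) & 1UL)) ++f;
    const double* slice = Mp + (size_t)f * nn;
    if ((gray >> f) & 1UL) {
      for (size_t q = 0; q < nn; ++q) D[q] += slice[q];
    } else {
      for (size_t q = 0; q < nn; ++q) D[q] -= slice[q];
    }
    prev_gray = gray;

    loocv_scores_from_D(D, n, y, k, sc.data(), buf);
    auc[t - 1] = auc_pairs(sc.data(), y, n);
    subset[t - 1] = (int)gray;
    if (keep_scores) {
      for (int i = 0; i < n; ++i) scores(i, (int)(t - 1)) = sc[i];
    }
  }
  if (keep_scores) {
    return List::create(_["subset"] = subset, _["auc"] = auc,
                        _["scores"] = scores);
  }
  return List::create(_["subset"] = subset, _["auc"] = auc);
}
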