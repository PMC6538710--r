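#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Sliding-window engine computing all twelve QUS parameters per window in
// one pass: NAK (Nakagami method of moments) and ENT (weighted entropy)
// from the envelope block, CON/COR/ENE/HOM/VAR from the vertical and
// horizontal GLCMs of the quantized B-mode block. Column order matches
// QUS_PARAMS. Estimation failures yield NA.
//
// env:   envelope image (isotropic grid)
// quant: B-mode gray levels 1..levels, same grid
// prow/pcol: 1-based window start indices (parallel vectors)
// wp: window side in px; d: GLCM displacement in px

static void glcm_feats(const std::vector<int>& counts, int L, long npairs,
                       double* out5) {
  std::vector<double> pi(L, 0.0), pj(L, 0.0);
  double inv = 1.0 / (double)npairs;
  double con = 0.0, ene = 0.0, hom = 0.0, sij = 0.0;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) {
      int c = counts[(size_t)i * L + j];
      if (!c) continue;
      double g = c * inv;
      double dd = (double)(i - j) * (i - j);
      con += dd * g;
      ene += g * g;
      hom += g / (1.0 + dd);
      sij += (double)(i + 1) * (j + 1) * g;
      pi[i] += g;
      pj[j] += g;
    }
  }
  double mui = 0.0, muj = 0.0;
  for (int i = 0; i < L; ++i) {
    mui += (i + 1) * pi[i];
    muj += (i + 1) * pj[i];
  }
  double vi = 0.0, vj = 0.0;
  for (int i = 0; i < L; ++i) {
    vi += ((i + 1) - mui) * ((i + 1) - mui) * pi[i];
    vj += ((i + 1) - muj) * ((i + 1) - muj) * pj[i];
  }
  double sdi = std::sqrt(vi), sdj = std::sqrt(vj);
  out5[0] = con;                                          // CON
  out5[1] = (sdi == 0.0 || sdj == 0.0) ? NA_REAL
            : (sij - mui * muj) / (sdi * sdj);            // COR
  out5[2] = ene;                                          // ENE
  out5[3] = hom;                                          // HOM
  out5[4] = vi;                                           // VAR
}

//' @noRd
// [[Rcpp::export(name = ".qus_maps_cpp")]]
NumericMatrix qus_maps_cpp(NumericMatrix env, IntegerMatrix quant,
                           IntegerVector prow, IntegerVector pcol,
                           int wp, int entropy_bins, int d, int levels) {
  const int npl = prow.size();
  const int nr = env.nrow();
  NumericMatrix out(npl, 12);
  std::fill(out.begin(), out.end(), NA_REAL);

  std::vector<double> block((size_t)wp * wp);
  std::vector<int> hist(entropy_bins);
  std::vector<int> counts((size_t)levels * levels);
  const double* envp = REAL(env);
  const int* qp = INTEGER(quant);
  const int qnr = quant.nrow();

  for (int q = 0; q < npl; ++q) {
    const int r0 = prow[q] - 1, c0 = pcol[q] - 1;
    const int n = wp * wp;

    // ---- envelope statistics -------------------------------------------
    double s = 0.0, s2 = 0.0, lo = R_PosInf, hi = R_NegInf;
    for (int c = 0; c < wp; ++c) {
      const double* col = envp + (size_t)(c0 + c) * nr + r0;
      for (int r = 0; r < wp; ++r) {
        double a = col[r];
        block[(size_t)c * wp + r] = a;
        s += a;
        s2 += a * a;
        if (a < lo) lo = a;
        if (a > hi) hi = a;
      }
    }
    double m2 = s2 / n;
    // two-pass population variance of A^2 (matches the R estimator)
    double v = 0.0;
    for (int t = 0; t < n; ++t) {
      double a2 = block[t] * block[t];
      v += (a2 - m2) * (a2 - m2);
    }
    v /= n;
    if (v > 0.0) out(q, 0) = m2 * m2 / v;  // NAK

    if (s > 0.0) {
      if (hi == lo) {
        out(q, 1) = 0.0;  // ENT: single occupied bin
      } else {
        std::fill(hist.begin(), hist.end(), 0);
        std::vector<int> bin(n);
        double scale = entropy_bins / (hi - lo);
        for (int t = 0; t < n; ++t) {
          int b = (int)std::floor((block[t] - lo) * scale);
          if (b >= entropy_bins) b = entropy_bins - 1;
          bin[t] = b;
          ++hist[b];
        }
        double ent = 0.0;
        for (int t = 0; t < n; ++t) {
          double p = hist[bin[t]] / (double)n;
          ent -= block[t] / s * p * std::log2(p);
        }
        out(q, 1) = ent;
      }
    }

    // ---- GLCM texture features -----------------------------------------
    // vertical: pixel paired with the one d rows below
    if (wp > d) {
      std::fill(counts.begin(), counts.end(), 0);
      for (int c = 0; c < wp; ++c) {
        const int* col = qp + (size_t)(c0 + c) * qnr + r0;
        for (int r = 0; r < wp - d; ++r) {
          ++counts[(size_t)(col[r] - 1) * levels + (col[r + d] - 1)];
        }
      }
      double f[5];
      glcm_feats(counts, levels, (long)wp * (wp - d), f);
      out(q, 2) = f[0];   // CONV
      out(q, 4) = f[1];   // CORV
      out(q, 6) = f[2];   // ENEV
      out(q, 8) = f[3];   // HOMV
      out(q, 10) = f[4];  // VARV

      // horizontal: pixel paired with the one d columns right
      std::fill(counts.begin(), counts.end(), 0);
      for (int c = 0; c < wp - d; ++c) {
        const int* colA = qp + (size_t)(c0 + c) * qnr + r0;
        const int* colB = qp + (size_t)(c0 + c + d) * qnr + r0;
        for (int r = 0; r < wp; ++r) {
          ++counts[(size_t)(colA[r] - 1) * levels + (colB[r] - 1)];
        }
      }
      glcm_feats(counts, levels, (long)wp * (wp - d), f);
      out(q, 3) = f[0];   // CONH
      out(q, 5) = f[1];   // CORH
      out(q, 7) = f[2];   // ENEH
      out(q, 9) = f[3];   // HOMH
      out(q, 11) = f[4];  // VARH
    }
  }
  return out;
}
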