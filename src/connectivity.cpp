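#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulators for the debiased wPLI at one frequency bin.
// Fr/Fi: epochs x R real/imaginary parts of the Fourier coefficients.
// Returns S1 = sum_e Im(X_ab), S2 = sum_e Im(X_ab)^2, S3 = sum_e |Im(X_ab)|
// with X_ab = F_a * conj(F_b).
// [[Rcpp::export(name = ".dwpli_sums")]]
List dwpli_sums(NumericMatrix Fr, NumericMatrix Fi) {
  int ne = Fr.nrow(), nr = Fr.ncol();
  NumericMatrix S1(nr, nr), S2(nr, nr), S3(nr, nr);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < nr; ++a) {
      double ra = Fr(e, a), ia = Fi(e, a);
      for (int b = a + 1; b < nr; ++b) {
        double im = ia * Fr(e, b) - ra * Fi(e, b);
        S1(a, b) += im;
        S2(a, b) += im * im;
        S3(a, b) += std::fabs(im);
      }
    }
  }
  for (int a = 0; a < nr; ++a)
    for (int b = a + 1; b < nr; ++b) {
      S1(b, a) = -S1(a, b);
      S2(b, a) = S2(a, b);
      S3(b, a) = S3(a, b);
    }
  return List::create(_["s1"] = S1, _["s2"] = S2, _["s3"] = S3);
}

// One epoch of pairwise orthogonalized envelope correlations.
// Zr/Zi: samples x R analytic signals. Returns R1 with
// R1(a,b) = corr(|A_orth_B|, |B|), where A_orth_B(t) = Im(A conj(B))/|B|.
// Degenerate (zero-variance) envelopes give 0.
// [[Rcpp::export(name = ".aec_corr_mat")]]
NumericMatrix aec_corr_mat(NumericMatrix Zr, NumericMatrix Zi) {
  int ns = Zr.nrow(), nr = Zr.ncol();
  NumericMatrix R1(nr, nr);
  std::vector<double> envb(ns), v(ns);
  for (int b = 0; b < nr; ++b) {
    double meb = 0.0;
    for (int t = 0; t < ns; ++t) {
      envb[t] = std::sqrt(Zr(t, b) * Zr(t, b) + Zi(t, b) * Zi(t, b));
      meb += envb[t];
    }
    meb /= ns;
    double ssb = 0.0;
    for (int t = 0; t < ns; ++t) ssb += (envb[t] - meb) * (envb[t] - meb);
    for (int a = 0; a < nr; ++a) {
      if (a == b) continue;
      double mv = 0.0;
      for (int t = 0; t < ns; ++t) {
        double im = Zi(t, a) * Zr(t, b) - Zr(t, a) * Zi(t, b);
        double den = envb[t] > 1e-300 ? envb[t] : 1e-300;
        v[t] = std::fabs(im) / den;
        mv += v[t];
      }
      mv /= ns;
      double ssv = 0.0, sxy = 0.0;
      for (int t = 0; t < ns; ++t) {
        ssv += (v[t] - mv) * (v[t] - mv);
        sxy += (v[t] - mv) * (envb[t] - meb);
      }
      if (ssv < 1e-20 || ssb < 1e-20) R1(a, b) = 0.0;
      else R1(a, b) = sxy / std::sqrt(ssv * ssb);
    }
  }
  return R1;
}
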