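#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// |W| of a (time x scale) complex CWT matrix, returned transposed as the
// (frequency x time) scalogram magnitude
// [[Rcpp::export]]
NumericMatrix mag_transpose_cpp(ComplexMatrix W) {
  const int nt = W.nrow(), ns = W.ncol();
  NumericMatrix M(ns, nt);
  for (int s = 0; s < ns; ++s)
    for (int t = 0; t < nt; ++t) {
      const Rcomplex z = W(t, s);
      M(s, t) = std::sqrt(z.r * z.r + z.i * z.i);
    }
  return M;
}

// mean |M[f+k2, t+k1] - M[f, t]| over valid cells of a (frequency x time)
// magnitude matrix
// [[Rcpp::export]]
double flux_mean_cpp(NumericMatrix M, int k1, int k2) {
  const int nf = M.nrow(), nt = M.ncol();
  double acc = 0.0;
  for (int t = 0; t < nt - k1; ++t)
    for (int f = 0; f < nf - k2; ++f)
      acc += std::fabs(M(f + k2, t + k1) - M(f, t));
  return acc / ((double)(nf - k2) * (nt - k1));
}
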