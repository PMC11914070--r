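#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nonlinear term of the spatio-temporal INRF at one sensor location.
//
// P:      S x T matrix; column t holds the w-kernel support patch of
//         frame t (S = number of kernel pixels, vectorised in the same
//         order as wvec).
// wvec:   Gabor weights over the support (length S).
// center: sensor-pixel trace I(s_i, t) (length T).
// tw:     lowpass temporal taps, tw[k] multiplies the patch at delay k
//         frames.
// p, q:   nonlinearity exponent and half-saturation.
//
// Returns, for each frame t with full temporal support,
//   sum_k tw[k] * sum_j w[j] * sigma(P[j, t-k] - center[t]);
// frames without full support are NA.  The shift of sigma uses the
// CURRENT frame value center[t] at every delay.
// [[Rcpp::export]]
NumericVector stinrf_nonlinear_core(const NumericMatrix& P,
                                    const NumericVector& wvec,
                                    const NumericVector& center,
                                    const NumericVector& tw,
                                    double p, double q) {
  const int S = P.nrow(), T = P.ncol(), K = tw.size();
  const double qp = std::pow(q, p);
  NumericVector out(T, NA_REAL);
  for (int t = K - 1; t < T; ++t) {
    const double c = center[t];
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      const double* col = &P(0, t - k);
      double s = 0.0;
      for (int j = 0; j < S; ++j) {
        const double z = std::fabs(col[j] - c);
        const double zp = std::pow(z, p);
        s += wvec[j] * (zp / (zp + qp));
      }
      acc += tw[k] * s;
    }
    out[t] = acc;
  }
  return out;
}
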