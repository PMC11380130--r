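#include <Rcpp.h>

using namespace Rcpp;

// Cascade of biquad sections in transposed direct form II.
// sos: n_sections x 6 (b0 b1 b2 a0 a1 a2), a0 == 1.
// zi: n_sections x 2 initial state (already scaled by the caller).
// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericVector x, NumericMatrix sos, NumericMatrix zi) {
  const int n = x.size();
  const int ns = sos.nrow();
  NumericVector y(clone(x));
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi(s, 0), z2 = zi(s, 1);
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
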