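#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed filtering of one biquad cascade.
// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1.
// zi: n_sections x 2 initial conditions (modified in place on a copy).
// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const int n = x.size();
  NumericVector y(n);
  NumericMatrix z = clone(zi);
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      const double w = v;
      v = b0 * w + z(s, 0);
      z(s, 0) = b1 * w - a1 * v + z(s, 1);
      z(s, 1) = b2 * w - a2 * v;
    }
    y[i] = v;
  }
  return y;
}
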