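#include <Rcpp.h>
using namespace Rcpp;

// Cascaded biquad (second-order-section) filtering, direct form II transposed.
// sos: k x 6 matrix, rows (b0, b1, b2, a0, a1, a2) with a0 == 1.

// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int n = x.size(), k = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < k; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    // steady-state initial conditions for a step of the first sample,
    // so constant inputs produce no startup transient
    const double x0 = y[0];
    const double den = 1.0 + a1 + a2;
    const double y0 = (std::abs(den) > 1e-12)
                        ? x0 * (b0 + b1 + b2) / den : 0.0;
    double z2 = b2 * x0 - a2 * y0;
    double z1 = b1 * x0 - a1 * y0 + z2;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
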