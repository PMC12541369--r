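#include <Rcpp.h>
using namespace Rcpp;

// Weighted isotropic Gaussian mixture density evaluated at query points.
//
// Both shape models (hollow ring, filled ellipse) reduce, after quadrature,
// to a probability measure carried by nodes (qx, qy) with weights qw summing
// to 1, convolved with a per-point Gaussian of SD prec[i] (the localization
// precision). Density at point i:
//   d_i = sum_j qw_j * exp(-r_ij^2 / (2 s_i^2)) / (2 pi s_i^2)
//
// prec must have the same length as px/py; callers recycle scalars.
// [[Rcpp::export]]
NumericVector gauss_mixture_density_cpp(NumericVector px, NumericVector py,
                                        NumericVector prec,
                                        NumericVector qx, NumericVector qy,
                                        NumericVector qw) {
  const int n = px.size();
  const int m = qx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double s2 = prec[i] * prec[i];
    const double norm = 1.0 / (2.0 * M_PI * s2);
    const double inv = -0.5 / s2;
    double acc = 0.0;
    const double xi = px[i], yi = py[i];
    // contributions with exponent < -34 (< 2e-15 relative) are dropped
    const double r2max = 34.0 * 2.0 * s2;
    for (int j = 0; j < m; ++j) {
      const double dx = xi - qx[j];
      const double dy = yi - qy[j];
      const double r2 = dx * dx + dy * dy;
      if (r2 < r2max) acc += qw[j] * std::exp(inv * r2);
    }
    out[i] = norm * acc;
  }
  return out;
}
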