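#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Steady-state (CW) free-field summation of monopole sub-sources.
//
// pts:     n x 3 observation points [m]
// src:     m x 3 sub-source centres [m]
// area:    m    sub-source areas [m^2]
// delay_s: m    per-sub-source firing delays [s]
// k:       wavenumber omega/c0 [rad/m]
// omega:   angular frequency [rad/s]
// alpha:   amplitude attenuation [Np/m]
// amplitude: drive scale (linear)
//
// Each sub-source contributes amplitude * area/(2*pi*R) * exp(-alpha R)
// * exp(i (k R + omega * delay)).  All inputs strictly SI.
// [[Rcpp::export]]
ComplexVector cw_source_sum(NumericMatrix pts, NumericMatrix src,
                            NumericVector area, NumericVector delay_s,
                            double k, double omega, double alpha,
                            double amplitude) {
  const int n = pts.nrow();
  const int m = src.nrow();
  if (src.ncol() != 3 || pts.ncol() != 3)
    stop("positions must be n x 3 matrices");
  if (area.size() != m || delay_s.size() != m)
    stop("area/delay length must match the number of sub-sources");

  std::vector<double> sx(m), sy(m), sz(m), w(m), ph0(m);
  for (int j = 0; j < m; ++j) {
    sx[j] = src(j, 0);
    sy[j] = src(j, 1);
    sz[j] = src(j, 2);
    w[j] = area[j] / (2.0 * M_PI);
    ph0[j] = omega * delay_s[j];
  }

  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double re = 0.0, im = 0.0;
    for (int j = 0; j < m; ++j) {
      const double dx = px - sx[j];
      const double dy = py - sy[j];
      const double dz = pz - sz[j];
      const double R = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (R <= 0.0)
        stop("observation point coincides with a sub-source (R = 0)");
      double g = w[j] / R;
      if (alpha > 0.0) g *= std::exp(-alpha * R);
      const double ph = k * R + ph0[j];
      re += g * std::cos(ph);
      im += g * std::sin(ph);
    }
    Rcomplex z;
    z.r = amplitude * re;
    z.i = amplitude * im;
    out[i] = z;
  }
  return out;
}
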