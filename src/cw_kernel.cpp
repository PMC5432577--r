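#include <Rcpp.h>
#include <complex>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Choi-Williams smoothed instantaneous autocorrelation, with an
// additional fixed time-smoothing window as in standard discrete
// implementations of Cohen-class distributions.
//
// For each requested time instant n (0-based) and lag m = 0..max_lag-1:
//   K(n, m) = sum_p w_m(p) z[n+p+m] conj(z[n+p-m])
// where w_m is a Gaussian of standard deviation
//   sd_m = sqrt(2 m^2 / sigma + s0^2)
// (the exponential Choi-Williams kernel, whose time spread grows with the
// lag, convolved with a fixed Gaussian time window of sd s0 samples that
// also smooths the small-lag terms the CW kernel leaves untouched),
// normalized to unit sum, truncated at 2.5 sd and capped at +/- p_max
// samples. Samples outside the segment are treated as zero. The weights
// depend only on the lag, so they are precomputed once per lag.
//
// [[Rcpp::export]]
ComplexMatrix cw_kernel(ComplexVector z, IntegerVector t_idx,
                        int max_lag, double sigma, double s0, int p_max) {
  const int N = z.size();
  const int T = t_idx.size();
  std::vector<std::complex<double> > zz(N);
  for (int i = 0; i < N; ++i)
    zz[i] = std::complex<double>(z[i].r, z[i].i);
  ComplexMatrix K(max_lag, T);

  std::vector<double> w;
  for (int m = 0; m < max_lag; ++m) {
    const double sd = std::sqrt(2.0 * m * m / sigma + s0 * s0);
    int h = (int)std::ceil(2.5 * sd);
    if (h > p_max) h = p_max;
    if (h < 0) h = 0;
    w.assign(2 * h + 1, 0.0);
    double wsum = 0.0;
    const double c = (sd > 0.0) ? 1.0 / (2.0 * sd * sd) : 0.0;
    for (int p = -h; p <= h; ++p) {
      const double v = std::exp(-c * (double)p * (double)p);
      w[p + h] = v;
      wsum += v;
    }
    for (int q = 0; q <= 2 * h; ++q) w[q] /= wsum;
    for (int ti = 0; ti < T; ++ti) {
      const int n = t_idx[ti];
      int plo = -h, phi = h;
      // clip p so both n+p+m and n+p-m stay inside [0, N)
      if (n - h - m < 0) plo = m - n;
      if (n + h + m > N - 1) phi = N - 1 - n - m;
      std::complex<double> acc(0.0, 0.0);
      for (int p = plo; p <= phi; ++p)
        acc += w[p + h] * zz[n + p + m] * std::conj(zz[n + p - m]);
      K(m, ti) = Rcomplex{acc.real(), acc.imag()};
    }
  }
  return K;
}
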