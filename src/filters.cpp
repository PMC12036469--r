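// Second-order-section cascade filtering and windowed-sinc rational
// resampling. Both are performance-critical: every channel of every
// recording passes through them twice (forward and reversed).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Direct form II transposed biquad cascade, single pass.
// sos is k x 6: b0 b1 b2 a0 a1 a2 per row (a0 == 1 after normalization).
// [[Rcpp::export]]
NumericVector cpp_sosfilt(const NumericMatrix &sos, const NumericVector &x) {
  const int n = x.size(), k = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < k; ++s) {
    const double a0 = sos(s, 3);
    const double b0 = sos(s, 0) / a0, b1 = sos(s, 1) / a0, b2 = sos(s, 2) / a0;
    const double a1 = sos(s, 4) / a0, a2 = sos(s, 5) / a0;
    double z1 = 0.0, z2 = 0.0;
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

// Windowed-sinc (Hamming) rational resampler. Symmetric kernel (zero phase),
// cutoff at the lower of the two Nyquist frequencies; weights renormalized
// per output sample so constants are preserved exactly, including at edges.
// For a rational rate ratio p/q the kernel phases repeat with period p, so
// tap tables are precomputed per phase.
// [[Rcpp::export]]
NumericVector cpp_resample(const NumericVector &x, double from_rate,
                           double to_rate, int lobes = 10) {
  const int n = x.size();
  // reduce the ratio to lowest terms (rates resolved to 1/1000 Hz)
  long a = static_cast<long>(std::lround(to_rate * 1000));
  long b = static_cast<long>(std::lround(from_rate * 1000));
  long g0 = a, g1 = b;
  while (g1 != 0) { long t = g0 % g1; g0 = g1; g1 = t; }
  const long p = a / g0, q = b / g0;
  const double ratio = static_cast<double>(p) / q;
  const int m = static_cast<int>(std::floor(n * ratio + 0.5));
  NumericVector y(m);
  const double fc = 0.5 * std::min(1.0, ratio);   // cycles per input sample
  const double hw = lobes / (2.0 * fc);           // kernel half-width, input samples
  // per-phase taps: phase jp has center offset cp = jp*q/p
  std::vector<std::vector<double>> taps(p);
  std::vector<int> lo_rel(p);
  std::vector<double> wsum(p);
  for (long jp = 0; jp < p; ++jp) {
    const double cp = static_cast<double>(jp) * q / p;
    const int lo = static_cast<int>(std::ceil(cp - hw));
    const int hi = static_cast<int>(std::floor(cp + hw));
    lo_rel[jp] = lo;
    std::vector<double> w(hi - lo + 1);
    double s = 0.0;
    for (int i = lo; i <= hi; ++i) {
      const double t = i - cp;
      const double st = 2.0 * fc * t;
      const double sinc = (std::abs(st) < 1e-12) ? 1.0
                          : std::sin(M_PI * st) / (M_PI * st);
      const double win = 0.54 + 0.46 * std::cos(M_PI * t / hw);
      w[i - lo] = sinc * win;
      s += w[i - lo];
    }
    taps[jp] = std::move(w);
    wsum[jp] = s;
  }
  for (int j = 0; j < m; ++j) {
    const long blk = j / p, jp = j % p;
    const long base = blk * q + lo_rel[jp];
    const std::vector<double> &w = taps[jp];
    const int k = static_cast<int>(w.size());
    double acc = 0.0;
    if (base >= 0 && base + k <= n) {           // interior: precomputed sum
      const double *xp = &x[base];
      for (int i = 0; i < k; ++i) acc += w[i] * xp[i];
      y[j] = acc / wsum[jp];
    } else {                                    // edge: renormalize in-range taps
      double s = 0.0;
      for (int i = 0; i < k; ++i) {
        const long ix = base + i;
        if (ix >= 0 && ix < n) { acc += w[i] * x[ix]; s += w[i]; }
      }
      y[j] = (s != 0.0) ? acc / s : 0.0;
    }
  }
  return y;
}
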