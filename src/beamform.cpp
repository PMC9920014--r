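// Windowed delay-and-sum / delay-multiply-and-sum accumulation kernels.
// signals: T x M (one column per channel); start: P x M fractional 0-based
// sample offset of the window start per (pixel, channel); wt: P x M channel
// weights. With interp = false the start offset is rounded to the nearest
// sample; with interp = true the two neighboring samples are blended.
// DMAS uses the pair-sum identity  sum_{i<j} a_i a_j = ((sum a)^2 - sum a^2)/2.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector beamform_core_cpp(NumericMatrix signals, NumericMatrix start,
                                NumericMatrix wt, int W, bool dmas,
                                bool interp = false) {
  const int T = signals.nrow();
  const int M = signals.ncol();
  const int P = start.nrow();
  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    double acc = 0.0;
    for (int w = 0; w < W; ++w) {
      double s = 0.0, s2 = 0.0;
      for (int m = 0; m < M; ++m) {
        double a;
        if (interp) {
          const double x = start(p, m) + w;
          const int i0 = (int)std::floor(x);
          if (i0 < 0 || i0 + 1 >= T) continue;
          const double f = x - i0;
          a = wt(p, m) * ((1.0 - f) * signals(i0, m) + f * signals(i0 + 1, m));
        } else {
          const int idx = (int)std::lround(start(p, m)) + w;
          if (idx < 0 || idx >= T) continue;
          a = wt(p, m) * signals(idx, m);
        }
        s += a;
        if (dmas) s2 += a * a;
      }
      const double v = dmas ? 0.5 * (s * s - s2) : s;
      acc += v * v;
    }
    out[p] = acc;
  }
  return out;
}
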