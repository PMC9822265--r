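#include <Rcpp.h>
using namespace Rcpp;

// Exact-propagator integration of the two-state subthreshold membrane
//   C dV/dt = -g_L (V - E_L) - a w + I(t)
//   tau_w dw/dt = (V - E_L) - w
// The per-step propagator E (2x2) and input matrix M = A^-1 (E - I) are
// precomputed in R from the eigendecomposition of the system matrix, so the
// step is exact for piecewise-constant input. State is x = (V - E_L, w).
//
// When spikes are enabled, a stereotyped template (absolute mV, starting at
// the threshold value) is pasted into the output whenever the dynamic V
// crosses V_T; the dynamic state resumes from V_r with w held constant over
// the template. Spike times are the threshold-crossing times.

// [[Rcpp::export]]
List gif_integrate_cpp(NumericVector I, double dt,
                       NumericMatrix E, NumericMatrix M,
                       double C, double EL,
                       double v0, double w0,
                       bool spikes_enabled,
                       double VT, double Vr,
                       NumericVector spike_template) {
  const int n = I.size();
  NumericVector out(n);
  const double e11 = E(0, 0), e12 = E(0, 1), e21 = E(1, 0), e22 = E(1, 1);
  const double m11 = M(0, 0), m21 = M(1, 0);
  const int tlen = spike_template.size();

  double v = v0, w = w0;  // deviations from E_L (v) and adaptation (w)
  out[0] = EL + v;
  std::vector<double> spike_times;

  int k = 1;
  while (k < n) {
    const double b1 = I[k - 1] / C;  // input held over [k-1, k)
    const double vn = e11 * v + e12 * w + m11 * b1;
    const double wn = e21 * v + e22 * w + m21 * b1;
    v = vn;
    w = wn;
    if (spikes_enabled && (EL + v) >= VT) {
      spike_times.push_back(k * dt);
      int j = 0;
      for (; j < tlen && (k + j) < n; ++j) out[k + j] = spike_template[j];
      // state at the end of the template: reset voltage, w carried over
      v = Vr - EL;
      k += (j > 0 ? j : 1);
      continue;
    }
    out[k] = EL + v;
    ++k;
  }

  return List::create(_["voltage"] = out,
                      _["spike_times"] = wrap(spike_times),
                      _["v_end"] = v, _["w_end"] = w);
}
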