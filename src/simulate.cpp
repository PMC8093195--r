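#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-compartment conductance model: leak + HCN (Ih) gating variable +
// optional adaptive-exponential spike mechanism with a pasted stereotyped
// AP waveform so that ground-truth spike times stay exact.
//
// Units: V mV, t ms, C pF, g nS, I pA  (pF*mV/ms = pA).
// Fixed-step explicit Euler with `oversample` substeps per stimulus sample;
// the stimulus is held constant within a sample.
//
// [[Rcpp::export]]
List sim_neuron_cpp(NumericVector stim, double fs, List prm, int oversample) {
  const double C   = prm["C_pF"];
  const double gL  = prm["gL_nS"];
  const double EL  = prm["EL_mV"];
  const double gh  = prm["gh_nS"];
  const double Eh  = prm["Eh_mV"];
  const double V50 = prm["V50h_mV"];
  const double kh  = prm["kh_mV"];
  const double tauh = prm["tau_h_ms"];
  const bool adex  = as<std::string>(prm["spike"]) == "adex";
  const double VT  = prm["VT_mV"];
  const double DT  = prm["DeltaT_mV"];
  const double Vr  = prm["Vreset_mV"];
  const double a   = prm["a_nS"];
  const double b   = prm["b_pA"];
  const double tauw = prm["tau_w_ms"];
  const double appk = prm["ap_peak_mV"];
  const double aprise = prm["ap_rise_ms"];
  const double apfall = prm["ap_fall_ms"];
  const double V0  = prm["V0"];
  const double m0  = prm["m0"];
  const double w0  = prm["w0"];
  const double Vcut = adex ? (VT + 5.0 * DT) : 1e9;

  const int n = stim.size();
  const double dt = 1000.0 / (fs * oversample);
  NumericVector Vout(n), mout(n), wout(n);
  std::vector<int> spike_idx, peak_idx;

  double V = V0, m = m0, w = w0;
  // paste state: time since spike in ms, negative when not pasting
  double paste_t = -1.0;
  const double paste_len = aprise + apfall;
  const int peak_off = (int)std::lround(aprise * fs / 1000.0);

  for (int i = 0; i < n; ++i) {
    const double I = stim[i];
    for (int s = 0; s < oversample; ++s) {
      const double minf = 1.0 / (1.0 + std::exp((V - V50) / kh));
      m += dt * (minf - m) / tauh;
      if (adex) w += dt * (a * (V - EL) - w) / tauw;

      if (paste_t >= 0.0) {
        paste_t += dt;
        if (paste_t < aprise) {
          V = Vcut + (appk - Vcut) * (paste_t / aprise);
        } else if (paste_t < paste_len) {
          V = appk + (Vr - appk) * ((paste_t - aprise) / apfall);
        } else {
          V = Vr;
          paste_t = -1.0;
        }
        continue;
      }

      double Iexp = 0.0;
      if (adex) {
        double ex = (V - VT) / DT;
        if (ex > 30.0) ex = 30.0;  // overflow guard; spike fires anyway
        Iexp = gL * DT * std::exp(ex);
      }
      const double dV = (-gL * (V - EL) - gh * m * (V - Eh) - w + Iexp + I) / C;
      V += dt * dV;

      if (!std::isfinite(V) || (!adex && (V > 100.0 || V < -200.0)))
        stop("numerical divergence at sample %d (V = %f mV); reduce the time step",
             i + 1, V);

      if (adex && V >= Vcut) {
        spike_idx.push_back(i + 1);             // 1-based crossing sample
        peak_idx.push_back(i + 1 + peak_off);   // pasted-peak sample
        w += b;
        V = Vcut;
        paste_t = 0.0;
      }
    }
    Vout[i] = V; mout[i] = m; wout[i] = w;
  }
  return List::create(_["V"] = Vout, _["m"] = mout, _["w"] = wout,
                      _["spike_idx"] = wrap(spike_idx),
                      _["peak_idx"] = wrap(peak_idx));
}
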