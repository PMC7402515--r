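// Exponential integrate-and-fire point neuron driven by an arbitrary
// injected current.  Forward Euler at the stimulus sampling step with the
// exponential spike current's argument capped to keep the blow-up finite
// until the cutoff crossing; spike time recorded at the cutoff crossing,
// then reset and an absolute refractory hold.
// Units: mV, ms, nS, pF, pA (input current in nA).
#pragma GCC optimize("O3")
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".eif_simulate")]]
List eif_simulate(double C_pF, double gL_nS, double E_L,
                  double V_T, double Delta_T,
                  double V_reset, double t_ref_ms, double V_cut,
                  NumericVector I_nA, double dt,
                  double v_init, bool record_v) {
  const int nsteps = I_nA.size();
  std::vector<double> v_rec;
  if (record_v) v_rec.reserve(nsteps + 1);
  std::vector<double> spikes;

  double V = v_init;
  double refrac_until = -1.0;
  if (record_v) v_rec.push_back(V);

  for (int k = 0; k < nsteps; ++k) {
    double t = k * dt;
    if (t < refrac_until) {
      V = V_reset;
    } else {
      double arg = (V - V_T) / Delta_T;
      if (arg > 40.0) arg = 40.0;
      double dV = (gL_nS * (E_L - V) + gL_nS * Delta_T * std::exp(arg) +
                   I_nA[k] * 1000.0) * dt / C_pF;
      V += dV;
      if (!std::isfinite(V))
        stop("numerical divergence at t = %.4f ms (cutoff too high?)", t);
      if (V >= V_cut) {
        spikes.push_back(t + dt);
        V = V_reset;
        refrac_until = t + dt + t_ref_ms;
      }
    }
    if (record_v) v_rec.push_back(V);
  }
  List out = List::create(
    _["spikes_ms"] = NumericVector(spikes.begin(), spikes.end()),
    _["dt"] = dt, _["n_steps"] = nsteps);
  if (record_v) out["v"] = NumericVector(v_rec.begin(), v_rec.end());
  return out;
}
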