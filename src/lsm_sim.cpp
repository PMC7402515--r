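// Recurrent network of exponential integrate-and-fire neurons with
// current-based exponential synapses, per-edge Tsodyks-Markram short-term
// plasticity, transmission delays on a ring buffer, and per-neuron Poisson
// background input.  Fixed time step; membrane and synaptic decays use
// exact exponential factors; the eIF spike current is tabulated.
//
// Edge lists arrive in CSR layout keyed by presynaptic neuron.  Background
// noise draws from the R RNG, so runs are reproducible under set.seed().
// Units: mV, ms, nS, pF, pA.
#pragma GCC optimize("O3")
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".lsm_simulate")]]
List lsm_simulate(int n_neurons, int n_exc,
                  IntegerVector edge_ptr,    // length n_neurons + 1
                  IntegerVector edge_post,   // 0-based targets
                  NumericVector edge_w_pA,
                  IntegerVector edge_delay,  // steps
                  NumericVector edge_U, NumericVector edge_D,
                  NumericVector edge_F,
                  IntegerVector in_ptr,      // CSR by input channel
                  IntegerVector in_post,
                  NumericVector in_w_pA,
                  IntegerVector in_delay,
                  NumericVector input_t_ms,  // sorted input spike times
                  IntegerVector input_ch,    // 0-based channels
                  double C_pF, double gL_nS, double E_L,
                  double V_T, double Delta_T, double V_reset,
                  double t_ref_ms, double V_cut,
                  double tau_e_ms, double tau_i_ms,
                  double noise_rate_hz, double noise_w_pA,
                  double duration_ms, double dt,
                  double max_rate_hz) {
  const int nsteps = static_cast<int>(std::round(duration_ms / dt));
  const int ref_steps = static_cast<int>(std::round(t_ref_ms / dt));

  int max_delay = 1;
  for (int e = 0; e < edge_delay.size(); ++e)
    if (edge_delay[e] > max_delay) max_delay = edge_delay[e];
  for (int e = 0; e < in_delay.size(); ++e)
    if (in_delay[e] > max_delay) max_delay = in_delay[e];
  const int buflen = max_delay + 1;

  std::vector<double> buf_e(static_cast<size_t>(buflen) * n_neurons, 0.0);
  std::vector<double> buf_i(static_cast<size_t>(buflen) * n_neurons, 0.0);
  std::vector<double> V(n_neurons, E_L), Ie(n_neurons, 0.0),
      Ii(n_neurons, 0.0);
  std::vector<int> ref_until(n_neurons, -1);

  // STP state per recurrent edge
  const int n_edges = edge_post.size();
  std::vector<double> stp_R(n_edges, 1.0), stp_u(n_edges, 0.0),
      stp_t(n_edges, -1.0e300), inv_F(n_edges), inv_D(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    inv_F[e] = 1.0 / edge_F[e];
    inv_D[e] = 1.0 / edge_D[e];
  }

  const double de = std::exp(-dt / tau_e_ms);
  const double di = std::exp(-dt / tau_i_ms);

  // tabulated spike current psi(V) = gL * Delta_T * exp((V - V_T)/Delta_T)
  const double tab_vmin = -150.0, tab_dv = 0.02;
  const int tab_n =
      static_cast<int>((V_cut - tab_vmin) / tab_dv) + 2;
  std::vector<double> psi(tab_n);
  for (int i = 0; i < tab_n; ++i) {
    double v = tab_vmin + i * tab_dv;
    double arg = (v - V_T) / Delta_T;
    if (arg > 40.0) arg = 40.0;
    psi[i] = gL_nS * Delta_T * std::exp(arg);
  }

  // per-neuron Poisson background (R RNG)
  RNGScope rng;
  std::vector<double> noise_next(n_neurons, 1.0e300);
  const double noise_mean_ms =
      (noise_rate_hz > 0.0) ? 1000.0 / noise_rate_hz : 0.0;
  if (noise_rate_hz > 0.0)
    for (int i = 0; i < n_neurons; ++i)
      noise_next[i] = R::exp_rand() * noise_mean_ms;

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  const double max_spikes =
      max_rate_hz * n_neurons * duration_ms / 1000.0 + 1000.0;
  bool runaway = false;

  int in_cursor = 0;
  const int n_input_spikes = input_t_ms.size();
  const double dt_over_C = dt / C_pF;

  for (int k = 0; k < nsteps && !runaway; ++k) {
    const double t = k * dt;
    const int slot = k % buflen;
    double* be = &buf_e[static_cast<size_t>(slot) * n_neurons];
    double* bi = &buf_i[static_cast<size_t>(slot) * n_neurons];

    // feed-forward input spikes due now are deposited with their delays
    while (in_cursor < n_input_spikes && input_t_ms[in_cursor] <= t) {
      int ch = input_ch[in_cursor];
      for (int e = in_ptr[ch]; e < in_ptr[ch + 1]; ++e) {
        int s2 = (k + in_delay[e]) % buflen;
        buf_e[static_cast<size_t>(s2) * n_neurons + in_post[e]] +=
            in_w_pA[e];
      }
      ++in_cursor;
    }

    for (int i = 0; i < n_neurons; ++i) {
      double ie = Ie[i] * de + be[i];
      double ii = Ii[i] * di + bi[i];
      be[i] = 0.0;
      bi[i] = 0.0;
      if (noise_next[i] <= t) {
        do {
          ie += noise_w_pA;
          noise_next[i] += R::exp_rand() * noise_mean_ms;
        } while (noise_next[i] <= t);
      }
      Ie[i] = ie;
      Ii[i] = ii;
      if (k < ref_until[i]) continue;
      double v = V[i];
      int ti = static_cast<int>((v - tab_vmin) / tab_dv);
      if (ti < 0) ti = 0;
      if (ti >= tab_n) ti = tab_n - 1;
      v += dt_over_C * (gL_nS * (E_L - v) + psi[ti] + ie - ii);
      if (v >= V_cut) {
        double ts = t + dt;
        spike_t.push_back(ts);
        spike_id.push_back(i);
        V[i] = V_reset;
        ref_until[i] = k + 1 + ref_steps;
        // propagate through outgoing edges with short-term plasticity
        for (int e = edge_ptr[i]; e < edge_ptr[i + 1]; ++e) {
          double u_prev = stp_u[e], R_prev = stp_R[e];
          double u_new, R_new;
          if (stp_t[e] < -1.0e200) {
            u_new = edge_U[e];
            R_new = 1.0;
          } else {
            double isi = ts - stp_t[e];
            u_new = edge_U[e] +
                    u_prev * (1.0 - edge_U[e]) * std::exp(-isi * inv_F[e]);
            R_new = 1.0 + (R_prev * (1.0 - u_prev) - 1.0) *
                              std::exp(-isi * inv_D[e]);
          }
          stp_u[e] = u_new;
          stp_R[e] = R_new;
          stp_t[e] = ts;
          double w = edge_w_pA[e] * R_new * u_new;
          int s2 = (k + 1 + edge_delay[e]) % buflen;
          size_t idx = static_cast<size_t>(s2) * n_neurons + edge_post[e];
          if (i < n_exc)
            buf_e[idx] += w;
          else
            buf_i[idx] += w;
        }
        if (spike_t.size() > max_spikes) runaway = true;
      } else {
        V[i] = v;
      }
    }
    if ((k & 4095) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["spike_t_ms"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["runaway"] = runaway, _["dt"] = dt);
}
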