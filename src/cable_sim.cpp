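// Linearly implicit theta-method integrator for the discretized soma + axon
// cable with Hodgkin-Huxley-type Na (m^3 h) and delayed-rectifier K (n)
// currents.  theta = 1 is backward Euler; theta = 0.5 is Crank-Nicolson
// with staggered gate updates (second-order spike timing).  Gates advance
// by exponential Euler from tabulated rate functions; the voltage step
// solves a tridiagonal system (Thomas algorithm).
//
// Units: mV, ms, nS, pF, pA.  Injected current is supplied in nA and scaled
// here.  Gate rate functions are tabulated on a fixed voltage grid so the
// per-step cost is a handful of table reads.
#pragma GCC optimize("O3")
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

constexpr double V_TAB_MIN = -150.0;
constexpr double V_TAB_MAX = 100.0;
constexpr double V_TAB_DV = 0.02;
const int V_TAB_N = static_cast<int>((V_TAB_MAX - V_TAB_MIN) / V_TAB_DV) + 1;

// x / (1 - exp(-x)) with the removable singularity at x = 0 filled in.
inline double efun(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 / (1.0 - 0.5 * x);
  return x / (1.0 - std::exp(-x));
}

// gate tables interleaved per voltage grid point so one lookup touches a
// single pair of cache lines: [m_inf, m_step, h_inf, h_step, n_inf, n_step]
// with step = 1 - exp(-dt / tau)
struct GateTab {
  std::vector<double> row;
  GateTab() : row(static_cast<size_t>(V_TAB_N) * 6) {}
};

struct Kinetics {
  // Na activation
  double na_tha, na_qa, na_Ra, na_Rb;
  // Na inactivation (rate constants for tau, Boltzmann for steady state)
  double na_thi1, na_thi2, na_qi, na_Rd, na_Rg, na_thinf, na_qinf;
  // K activation
  double kv_tha, kv_qa, kv_Ra, kv_Rb;
  double tadj;   // temperature scaling of all rates
  double vshift; // global shift applied to channel voltage dependence
};

Kinetics kin_from(const NumericVector& k) {
  Kinetics q;
  q.na_tha = k["na_tha"]; q.na_qa = k["na_qa"];
  q.na_Ra = k["na_Ra"];   q.na_Rb = k["na_Rb"];
  q.na_thi1 = k["na_thi1"]; q.na_thi2 = k["na_thi2"]; q.na_qi = k["na_qi"];
  q.na_Rd = k["na_Rd"]; q.na_Rg = k["na_Rg"];
  q.na_thinf = k["na_thinf"]; q.na_qinf = k["na_qinf"];
  q.kv_tha = k["kv_tha"]; q.kv_qa = k["kv_qa"];
  q.kv_Ra = k["kv_Ra"];   q.kv_Rb = k["kv_Rb"];
  q.tadj = k["tadj"]; q.vshift = k["vshift"];
  return q;
}

void na_m_rates(const Kinetics& k, double v, double& a, double& b) {
  a = k.na_Ra * k.na_qa * efun((v - k.na_tha) / k.na_qa);
  b = k.na_Rb * k.na_qa * efun(-(v - k.na_tha) / k.na_qa);
}
void na_h_rates(const Kinetics& k, double v, double& a, double& b) {
  a = k.na_Rd * k.na_qi * efun((v - k.na_thi1) / k.na_qi);
  b = k.na_Rg * k.na_qi * efun(-(v - k.na_thi2) / k.na_qi);
}
void kv_n_rates(const Kinetics& k, double v, double& a, double& b) {
  a = k.kv_Ra * k.kv_qa * efun((v - k.kv_tha) / k.kv_qa);
  b = k.kv_Rb * k.kv_qa * efun(-(v - k.kv_tha) / k.kv_qa);
}

void build_tables(const Kinetics& k, double dt, GateTab& tab) {
  for (int i = 0; i < V_TAB_N; ++i) {
    double v = V_TAB_MIN + i * V_TAB_DV - k.vshift;
    double a, b, tau;
    double* r = &tab.row[static_cast<size_t>(i) * 6];
    na_m_rates(k, v, a, b);
    tau = 1.0 / (k.tadj * (a + b));
    r[0] = a / (a + b);
    r[1] = 1.0 - std::exp(-dt / tau);
    na_h_rates(k, v, a, b);
    tau = 1.0 / (k.tadj * (a + b));
    r[2] = 1.0 / (1.0 + std::exp((v - k.na_thinf) / k.na_qinf));
    r[3] = 1.0 - std::exp(-dt / tau);
    kv_n_rates(k, v, a, b);
    tau = 1.0 / (k.tadj * (a + b));
    r[4] = a / (a + b);
    r[5] = 1.0 - std::exp(-dt / tau);
  }
}

inline int tab_index(double v) {
  int i = static_cast<int>((v - V_TAB_MIN) / V_TAB_DV + 0.5);
  if (i < 0) i = 0;
  if (i >= V_TAB_N) i = V_TAB_N - 1;
  return i;
}

// linear interpolation on the gate tables (position and weight)
inline void tab_locate(double v, int& i, double& w) {
  double u = (v - V_TAB_MIN) / V_TAB_DV;
  if (u < 0.0) u = 0.0;
  if (u > V_TAB_N - 1.001) u = V_TAB_N - 1.001;
  i = static_cast<int>(u);
  w = u - i;
}


} // namespace

// Steady-state gate values at a fixed voltage (used for initialisation and by
// the R-level oracle tests).
// [[Rcpp::export(name = ".gate_steady_state")]]
NumericVector gate_steady_state(double v, NumericVector kinetics) {
  Kinetics k = kin_from(kinetics);
  double vs = v - k.vshift, a, b;
  na_m_rates(k, vs, a, b);
  double minf = a / (a + b);
  double hinf = 1.0 / (1.0 + std::exp((vs - k.na_thinf) / k.na_qinf));
  kv_n_rates(k, vs, a, b);
  double ninf = a / (a + b);
  return NumericVector::create(_["m"] = minf, _["h"] = hinf, _["n"] = ninf);
}

// [[Rcpp::export(name = ".cable_simulate")]]
List cable_simulate(NumericVector C_pF,       // per-compartment capacitance
                    NumericVector gNa_nS,     // maximal conductances
                    NumericVector gK_nS,
                    NumericVector gL_nS,
                    NumericVector g_axial_nS, // coupling i <-> i+1
                    double E_Na, double E_K, double E_L,
                    NumericVector kinetics,
                    NumericVector I_nA,       // somatic current per step
                    double dt,
                    double v_init,
                    double spike_threshold,   // somatic detection level (mV)
                    double refractory_ms,     // detector lockout
                    int record,               // 0 none, 1 soma, 2 all
                    int record_stride,
                    double theta) {           // implicitness of the V step
  const int nc = C_pF.size();
  const int nsteps = I_nA.size();
  if (g_axial_nS.size() != nc - 1) stop("g_axial must have length ncomp - 1");
  if (record_stride < 1) record_stride = 1;

  Kinetics kin = kin_from(kinetics);
  GateTab tab;
  build_tables(kin, dt, tab);
  const double* tabp = tab.row.data();

  std::vector<double> V(nc, v_init), m(nc), h(nc), n(nc);
  {
    const double* r = tabp + static_cast<size_t>(tab_index(v_init)) * 6;
    for (int i = 0; i < nc; ++i) {
      m[i] = r[0]; h[i] = r[2]; n[i] = r[4];
    }
  }

  std::vector<double> lower(nc), diag(nc), upper(nc), rhs(nc), cp(nc), dp(nc);
  // step-invariant pieces of the theta-method system
  const double om_theta = 1.0 - theta;
  std::vector<double> a_over_dt(nc), gax_sum(nc, 0.0);
  for (int i = 0; i < nc; ++i) a_over_dt[i] = C_pF[i] / dt;
  for (int i = 0; i < nc; ++i) {
    if (i > 0) { gax_sum[i] += g_axial_nS[i - 1]; lower[i] = -theta * g_axial_nS[i - 1]; }
    if (i < nc - 1) { gax_sum[i] += g_axial_nS[i]; upper[i] = -theta * g_axial_nS[i]; }
  }
  std::vector<double> v_soma_rec;
  std::vector<double> v_all_rec;
  int nrec = (record > 0) ? (nsteps / record_stride + 1) : 0;
  if (record == 1) v_soma_rec.reserve(nrec);
  if (record == 2) v_all_rec.reserve(static_cast<size_t>(nrec) * nc);

  std::vector<double> spikes;
  double lockout_until = -1e300;
  double v_soma_prev = v_init;

  const double* Cp = C_pF.begin();
  const double* gNa = gNa_nS.begin();
  const double* gK = gK_nS.begin();
  const double* gL = gL_nS.begin();
  const double* gax = g_axial_nS.begin();

  if (record == 1) v_soma_rec.push_back(V[0]);
  if (record == 2) for (int i = 0; i < nc; ++i) v_all_rec.push_back(V[i]);

  for (int k = 0; k < nsteps; ++k) {
    // 1. gates by exponential Euler at the current voltage
    for (int i = 0; i < nc; ++i) {
      if (gNa[i] > 0.0 || gK[i] > 0.0) {
        int ti; double w;
        tab_locate(V[i], ti, w);
        const double* r0 = tabp + static_cast<size_t>(ti) * 6;
        const double* r1 = r0 + 6;
        double minf = r0[0] + w * (r1[0] - r0[0]);
        double mstp = r0[1] + w * (r1[1] - r0[1]);
        double hinf = r0[2] + w * (r1[2] - r0[2]);
        double hstp = r0[3] + w * (r1[3] - r0[3]);
        double ninf = r0[4] + w * (r1[4] - r0[4]);
        double nstp = r0[5] + w * (r1[5] - r0[5]);
        m[i] += mstp * (minf - m[i]);
        h[i] += hstp * (hinf - h[i]);
        n[i] += nstp * (ninf - n[i]);
      }
    }
    // 2. assemble the theta-method tridiagonal system for V at t + dt
    double I_soma_pA =
        (om_theta * I_nA[k] +
         theta * I_nA[(k + 1 < nsteps) ? k + 1 : k]) * 1000.0;
    for (int i = 0; i < nc; ++i) {
      double gna = gNa[i] * m[i] * m[i] * m[i] * h[i];
      double gk = gK[i] * n[i];
      double gtot = gna + gk + gL[i];
      double a = a_over_dt[i];
      diag[i] = a + theta * (gtot + gax_sum[i]);
      double r = (a - om_theta * gtot) * V[i] +
                 gna * E_Na + gk * E_K + gL[i] * E_L;
      if (i > 0) r += om_theta * gax[i - 1] * (V[i - 1] - V[i]);
      if (i < nc - 1) r += om_theta * gax[i] * (V[i + 1] - V[i]);
      rhs[i] = r;
    }
    rhs[0] += I_soma_pA;
    // 3. Thomas solve
    cp[0] = upper[0] / diag[0];
    dp[0] = rhs[0] / diag[0];
    for (int i = 1; i < nc; ++i) {
      double mlt = diag[i] - lower[i] * cp[i - 1];
      if (i < nc - 1) cp[i] = upper[i] / mlt;
      dp[i] = (rhs[i] - lower[i] * dp[i - 1]) / mlt;
    }
    V[nc - 1] = dp[nc - 1];
    for (int i = nc - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];

    double t = (k + 1) * dt;
    // 4. somatic spike detection with lockout
    if (V[0] >= spike_threshold && v_soma_prev < spike_threshold &&
        t >= lockout_until) {
      double frac = (spike_threshold - v_soma_prev) / (V[0] - v_soma_prev);
      spikes.push_back(t - dt + frac * dt);
      lockout_until = t + refractory_ms;
    }
    v_soma_prev = V[0];

    if (record == 1 && ((k + 1) % record_stride == 0))
      v_soma_rec.push_back(V[0]);
    if (record == 2 && ((k + 1) % record_stride == 0))
      for (int i = 0; i < nc; ++i) v_all_rec.push_back(V[i]);

    if ((k & 8191) == 0) {
      for (int i = 0; i < nc; ++i) {
        if (!std::isfinite(V[i]))
          stop("numerical divergence in compartment %d at t = %.4f ms",
               i, t);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  for (int i = 0; i < nc; ++i)
    if (!std::isfinite(V[i]))
      stop("numerical divergence in compartment %d at end of run", i);

  List out = List::create(
    _["spikes_ms"] = NumericVector(spikes.begin(), spikes.end()),
    _["v_final"] = NumericVector(V.begin(), V.end()),
    _["dt"] = dt, _["n_steps"] = nsteps);
  if (record == 1)
    out["v_soma"] = NumericVector(v_soma_rec.begin(), v_soma_rec.end());
  if (record == 2) {
    NumericMatrix M(nc, v_all_rec.size() / nc);
    std::copy(v_all_rec.begin(), v_all_rec.end(), M.begin());
    out["v_all"] = M;
  }
  return out;
}
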