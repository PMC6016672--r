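// Backward-Euler integration of the branched cable equation with
// Hodgkin-Huxley style gating. Gates are advanced by the exact
// exponential update at the step's voltage; the voltage system (linear
// once the gates are frozen) is solved by a tree-structured (Hines)
// elimination, O(n) per step.
//
// Units: mV, ms, uA (absolute currents), mS (absolute conductances),
// uF (absolute capacitances). The R layer converts densities to
// absolute quantities using compartment areas.
//
// The gate kinetics here must match the R mechanism library
// (R/mechanisms.R); the test suite pins the two against each other.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

static const double TAU_MIN = 0.02;

// classic HH sodium activation/inactivation
static inline void na_m(double v, double &minf, double &tau) {
  double a = 0.1 * vtrap(-(v + 40.0), 10.0);
  double b = 4.0 * std::exp(-(v + 65.0) / 18.0);
  minf = a / (a + b);
  tau = 1.0 / (a + b); if (tau < TAU_MIN) tau = TAU_MIN;
}
static inline void na_h(double v, double &minf, double &tau) {
  double a = 0.07 * std::exp(-(v + 65.0) / 20.0);
  double b = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  minf = a / (a + b);
  tau = 1.0 / (a + b); if (tau < TAU_MIN) tau = TAU_MIN;
}
// classic HH delayed-rectifier n
static inline void kdr_n(double v, double &minf, double &tau) {
  double a = 0.01 * vtrap(-(v + 55.0), 10.0);
  double b = 0.125 * std::exp(-(v + 65.0) / 80.0);
  minf = a / (a + b);
  tau = 1.0 / (a + b); if (tau < TAU_MIN) tau = TAU_MIN;
}
// Tunable kinetics of the A-type and reporter-calcium gates, set per
// simulation from the R mechanism library (see default_kinetics()).
// Layout: a_vhalf, a_k, a_tau, b_vhalf, b_k, b_tau_min, b_tau_amp,
//         b_tau_vhalf, b_tau_k, c_vhalf, c_k, c_tau
static double KIN[12];

// A-type activation (fast, depolarised midpoint)
static inline void ka_a(double v, double &minf, double &tau) {
  minf = 1.0 / (1.0 + std::exp(-(v - KIN[0]) / KIN[1]));
  tau = KIN[2];
}
// A-type inactivation (midpoint near rest; slow recovery at rest)
static inline void ka_b(double v, double &minf, double &tau) {
  minf = 1.0 / (1.0 + std::exp((v - KIN[3]) / KIN[4]));
  tau = KIN[5] + KIN[6] / (1.0 + std::exp((v - KIN[7]) / KIN[8]));
}
// reporter calcium activation (two identical gates, c^2)
static inline void ca_c(double v, double &minf, double &tau) {
  minf = 1.0 / (1.0 + std::exp(-(v - KIN[9]) / KIN[10]));
  tau = KIN[11];
}

typedef void (*rate_fn)(double, double &, double &);
static rate_fn GATE_RATES[6] = { na_m, na_h, kdr_n, ka_a, ka_b, ca_c };

// Voltage-indexed lookup tables for steady states and per-step decay
// factors, linearly interpolated (0.005 mV resolution); this is the
// usual table optimisation of compartmental simulators and can be
// switched off for verification against the R reference stepper.
struct RateTables {
  static const int NV = 46001;
  static constexpr double VMIN = -150.0, DV = 0.005;
  std::vector<double> minf[6], dec[6];
  void build(double dt) {
    for (int k = 0; k < 6; ++k) {
      minf[k].resize(NV); dec[k].resize(NV);
      for (int j = 0; j < NV; ++j) {
        double v = VMIN + j * DV, mi, tau;
        GATE_RATES[k](v, mi, tau);
        minf[k][j] = mi;
        dec[k][j] = std::exp(-dt / tau);
      }
    }
  }
  inline void look(int k, double v, double &mi, double &dc) const {
    double u = (v - VMIN) / DV;
    if (u < 0.0) u = 0.0;
    if (u > NV - 1.001) u = NV - 1.001;
    int j = (int)u;
    double w = u - j;
    mi = minf[k][j] + w * (minf[k][j + 1] - minf[k][j]);
    dc = dec[k][j] + w * (dec[k][j + 1] - dec[k][j]);
  }
};

// Gate order in the state matrix: m, h, n, a, b, c
// [[Rcpp::export]]
List cable_simulate_cpp(IntegerVector parent,       // 0-based, -1 root
                        NumericVector cm_uF,
                        NumericVector g_ax_mS,      // to parent, [0] unused
                        NumericVector gl_mS, NumericVector el,
                        NumericVector gna_mS, NumericVector gkdr_mS,
                        NumericVector gka_mS, NumericVector gca_mS,
                        double ena, double ek, double eca,
                        double dt, int n_steps, int sample_every,
                        NumericMatrix pulses,       // cols: idx0, on, off, uA
                        bool has_syn, int syn_comp0,
                        double syn_gmax_mS, double syn_tau1,
                        double syn_tau2, double syn_norm, double esyn,
                        NumericVector syn_onset_steps,
                        IntegerVector rec_v_idx0,
                        IntegerVector rec_ica_idx0,
                        int rec_gate_idx0,
                        NumericVector init_v, NumericMatrix init_gates,
                        NumericVector init_syn, bool use_tables,
                        NumericVector kin) {
  const int n = parent.size();
  if (kin.size() != 12) stop("kinetics vector must have length 12");
  for (int k = 0; k < 12; ++k) KIN[k] = kin[k];
  RateTables tables;
  if (use_tables) tables.build(dt);
  std::vector<double> v(init_v.begin(), init_v.end());
  std::vector<double> m(n), h(n), nn(n), ga(n), gb(n), gc(n);
  for (int i = 0; i < n; ++i) {
    m[i] = init_gates(i, 0); h[i] = init_gates(i, 1);
    nn[i] = init_gates(i, 2); ga[i] = init_gates(i, 3);
    gb[i] = init_gates(i, 4); gc[i] = init_gates(i, 5);
  }
  double synA = init_syn[0], synB = init_syn[1];
  const double dec1 = std::exp(-dt / syn_tau1);
  const double dec2 = std::exp(-dt / syn_tau2);

  const int n_samp = n_steps / sample_every + 1;
  const int nrv = rec_v_idx0.size(), nri = rec_ica_idx0.size();
  NumericMatrix out_v(n_samp, nrv), out_ica(n_samp, nri);
  NumericMatrix out_gates(n_samp, rec_gate_idx0 >= 0 ? 2 : 0);
  NumericVector out_t(n_samp), out_syn_g(n_samp);

  std::vector<double> diag(n), rhs(n);
  double min_v_all = R_PosInf, max_v_all = R_NegInf;

  // sort pulse steps once
  const int n_pulse = pulses.nrow();
  const int n_ev = syn_onset_steps.size();

  auto record = [&](int samp, double t) {
    out_t[samp] = t;
    for (int j = 0; j < nrv; ++j) out_v(samp, j) = v[rec_v_idx0[j]];
    for (int j = 0; j < nri; ++j) {
      int i = rec_ica_idx0[j];
      // current density uA/cm2: (gca_mS/area) handled in R via area;
      // here report absolute current in nA: mS*mV = uA -> *1e3 = nA
      double ica = gca_mS[i] * gc[i] * gc[i] * (v[i] - eca) * 1e3;
      out_ica(samp, j) = ica;
    }
    if (rec_gate_idx0 >= 0) {
      out_gates(samp, 0) = ga[rec_gate_idx0];
      out_gates(samp, 1) = gb[rec_gate_idx0];
    }
    double g_syn = has_syn ? syn_gmax_mS * syn_norm * (synB - synA) : 0.0;
    out_syn_g[samp] = g_syn * 1e6;  // mS -> nS
  };

  for (int i = 0; i < n; ++i) {
    if (v[i] < min_v_all) min_v_all = v[i];
    if (v[i] > max_v_all) max_v_all = v[i];
  }
  record(0, 0.0);

  int ev_ptr = 0;
  for (int s = 1; s <= n_steps; ++s) {
    // 1. gates: exact exponential update at the step's voltage
    if (use_tables) {
      for (int i = 0; i < n; ++i) {
        double mi, dc, vi = v[i];
        tables.look(0, vi, mi, dc); m[i] = mi + (m[i] - mi) * dc;
        tables.look(1, vi, mi, dc); h[i] = mi + (h[i] - mi) * dc;
        tables.look(2, vi, mi, dc); nn[i] = mi + (nn[i] - mi) * dc;
        tables.look(3, vi, mi, dc); ga[i] = mi + (ga[i] - mi) * dc;
        tables.look(4, vi, mi, dc); gb[i] = mi + (gb[i] - mi) * dc;
        tables.look(5, vi, mi, dc); gc[i] = mi + (gc[i] - mi) * dc;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double minf, tau, vi = v[i];
        na_m(vi, minf, tau); m[i] = minf + (m[i] - minf) * std::exp(-dt / tau);
        na_h(vi, minf, tau); h[i] = minf + (h[i] - minf) * std::exp(-dt / tau);
        kdr_n(vi, minf, tau); nn[i] = minf + (nn[i] - minf) * std::exp(-dt / tau);
        ka_a(vi, minf, tau); ga[i] = minf + (ga[i] - minf) * std::exp(-dt / tau);
        ka_b(vi, minf, tau); gb[i] = minf + (gb[i] - minf) * std::exp(-dt / tau);
        ca_c(vi, minf, tau); gc[i] = minf + (gc[i] - minf) * std::exp(-dt / tau);
      }
    }
    // 2. synapse two-state kinetics + scheduled events
    if (has_syn) {
      synA *= dec1; synB *= dec2;
      while (ev_ptr < n_ev && (int)syn_onset_steps[ev_ptr] == s) {
        synA += 1.0; synB += 1.0; ++ev_ptr;
      }
    }
    // 3. assemble backward-Euler system
    for (int i = 0; i < n; ++i) {
      double gi = gl_mS[i];
      double rhsi = cm_uF[i] / dt * v[i] + gl_mS[i] * el[i];
      if (gna_mS[i] > 0.0) {
        double g = gna_mS[i] * m[i] * m[i] * m[i] * h[i];
        gi += g; rhsi += g * ena;
      }
      if (gkdr_mS[i] > 0.0) {
        double g = gkdr_mS[i] * nn[i] * nn[i] * nn[i] * nn[i];
        gi += g; rhsi += g * ek;
      }
      if (gka_mS[i] > 0.0) {
        double g = gka_mS[i] * ga[i] * gb[i];
        gi += g; rhsi += g * ek;
      }
      if (gca_mS[i] > 0.0) {
        double g = gca_mS[i] * gc[i] * gc[i];
        gi += g; rhsi += g * eca;
      }
      diag[i] = cm_uF[i] / dt + gi;
      rhs[i] = rhsi;
    }
    if (has_syn) {
      double g_syn = syn_gmax_mS * syn_norm * (synB - synA);
      if (g_syn < 0.0) g_syn = 0.0;
      diag[syn_comp0] += g_syn;
      rhs[syn_comp0] += g_syn * esyn;
    }
    for (int p = 0; p < n_pulse; ++p) {
      if (s > pulses(p, 1) && s <= pulses(p, 2))
        rhs[(int)pulses(p, 0)] += pulses(p, 3);
    }
    // axial terms
    for (int i = 1; i < n; ++i) {
      diag[i] += g_ax_mS[i];
      diag[parent[i]] += g_ax_mS[i];
    }
    // 4. Hines elimination: leaves -> root, then back-substitution
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = g_ax_mS[i] / diag[i];
      diag[p] -= g_ax_mS[i] * f;
      rhs[p] += rhs[i] * f;
    }
    if (!(std::fabs(diag[0]) > 0.0) || !std::isfinite(diag[0]))
      stop("solver failure: singular system");
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + g_ax_mS[i] * v[parent[i]]) / diag[i];

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i])) stop("solver failure: non-finite voltage");
      if (v[i] < min_v_all) min_v_all = v[i];
      if (v[i] > max_v_all) max_v_all = v[i];
    }
    if (s % sample_every == 0) record(s / sample_every, s * dt);
  }

  NumericMatrix final_gates(n, 6);
  for (int i = 0; i < n; ++i) {
    final_gates(i, 0) = m[i]; final_gates(i, 1) = h[i];
    final_gates(i, 2) = nn[i]; final_gates(i, 3) = ga[i];
    final_gates(i, 4) = gb[i]; final_gates(i, 5) = gc[i];
  }
  return List::create(
    _["time"] = out_t, _["v"] = out_v, _["ica"] = out_ica,
    _["gates"] = out_gates, _["syn_g"] = out_syn_g,
    _["final_v"] = NumericVector(v.begin(), v.end()),
    _["final_gates"] = final_gates,
    _["final_syn"] = NumericVector::create(synA, synB),
    _["min_v_all"] = min_v_all, _["max_v_all"] = max_v_all);
}
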