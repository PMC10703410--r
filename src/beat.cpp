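// Beat-resolved cardiovascular loop: one-fiber LV, elastance RV, four
// compliant vascular segments, smoothed-diode valves. Fixed-step RK4 over one
// beat, iterated to a beat-periodic steady state. Units: mL, s, mmHg.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct BeatPars {
  // cardiac
  double c, sigma_ar, beta;
  double cf_myo, cf_ecm, phi_myo, phi_ecm; // homogeneous: equal cf, phi=(1,0)
  double V0p, Vw;
  double t_r, t_f, dt_f, t_beat;
  double l_s0, l_sf0, k_fsig, v_max, c_v, k_len, h_len_max, tau_v;
  // right ventricle
  double E_rv, C_rv, V_rv0;
  // circulation
  double C_sa, V0_sa, C_sv, V0_sv, C_pa, V0_pa, C_pv, V0_pv;
  double R_mit, R_av, R_sys, R_tri, R_pvalve, R_pulm;
  double eps_valve;
};

static BeatPars unpack(const List& par) {
  BeatPars p;
  p.c = par["c"]; p.sigma_ar = par["sigma_ar"]; p.beta = par["beta"];
  p.cf_myo = par["cf_myo"]; p.cf_ecm = par["cf_ecm"];
  p.phi_myo = par["phi_myo"]; p.phi_ecm = par["phi_ecm"];
  p.V0p = par["V0p"]; p.Vw = par["Vw"];
  p.t_r = par["t_r"]; p.t_f = par["t_f"]; p.dt_f = par["dt_f"];
  p.t_beat = par["t_beat"];
  p.l_s0 = par["l_s0"]; p.l_sf0 = par["l_sf0"]; p.k_fsig = par["k_fsig"];
  p.v_max = par["v_max"]; p.c_v = par["c_v"]; p.k_len = par["k_len"];
  p.h_len_max = par["h_len_max"]; p.tau_v = par["tau_v"];
  p.E_rv = par["E_rv"]; p.C_rv = par["C_rv"]; p.V_rv0 = par["V_rv0"];
  p.C_sa = par["C_sa"]; p.V0_sa = par["V0_sa"];
  p.C_sv = par["C_sv"]; p.V0_sv = par["V0_sv"];
  p.C_pa = par["C_pa"]; p.V0_pa = par["V0_pa"];
  p.C_pv = par["C_pv"]; p.V0_pv = par["V0_pv"];
  p.R_mit = par["R_mit"]; p.R_av = par["R_av"]; p.R_sys = par["R_sys"];
  p.R_tri = par["R_tri"]; p.R_pvalve = par["R_pvalve"]; p.R_pulm = par["R_pulm"];
  p.eps_valve = par["eps_valve"];
  return p;
}

static inline double g_act(double t, const BeatPars& p) {
  if (t < p.t_r) {
    double s = std::sin(M_PI * t / (2.0 * p.t_r));
    return s * s;
  }
  double fall = p.t_f + p.dt_f;
  if (t < p.t_r + fall) {
    double c = std::cos(M_PI * (t - p.t_r) / (2.0 * fall));
    return c * c;
  }
  return 0.0;
}

static inline double f_ls(double ls, const BeatPars& p) {
  if (ls < 1.4) ls = 1.4;
  if (ls > 3.0) ls = 3.0;
  return 1.0 / (1.0 + std::exp(-(ls - p.l_sf0) / p.k_fsig));
}

static inline double h_vs(double v, const BeatPars& p) {
  double vv = v / p.v_max;
  if (v >= 0.0) {
    if (vv >= 1.0) return 0.0;
    return (1.0 - vv) / (1.0 + p.c_v * vv);
  }
  double h = 1.0 + p.k_len * (-vv);
  return h > p.h_len_max ? p.h_len_max : h;
}

static inline double diode(double dP, double R, double eps) {
  // smoothed valve: conductance ramps up over ~eps mmHg
  double x = dP / eps;
  double s;
  if (x > 40.0) s = 1.0;
  else if (x < -40.0) s = 0.0;
  else s = 1.0 / (1.0 + std::exp(-x));
  return dP / R * s;
}

// instantaneous algebra shared by the RHS and the recorder
struct Alg {
  double lam, ls, g, sig_p, sig_a, P_lv, P_rv, P_sa, P_sv, P_pa, P_pv;
  double q_mit, q_av, q_sys, q_tri, q_pv, q_pulm;
};

static inline void algebra(double t, const double* y, const BeatPars& p, Alg& a) {
  double V_lv = y[0], V_rv = y[1], V_sa = y[2], V_sv = y[3],
         V_pa = y[4], V_pv = y[5], v_s = y[6];
  a.lam = std::cbrt((V_lv + p.Vw / 3.0) / (p.V0p + p.Vw / 3.0));
  a.ls = p.l_s0 * a.lam;
  a.g = g_act(t, p);
  a.sig_p = p.phi_myo * p.beta * (std::exp(p.cf_myo * (a.lam - 1.0)) - 1.0)
          + p.phi_ecm * p.beta * (std::exp(p.cf_ecm * (a.lam - 1.0)) - 1.0);
  a.sig_a = p.c * p.sigma_ar * f_ls(a.ls, p) * a.g * h_vs(v_s, p);
  a.P_lv = (a.sig_p + a.sig_a) / 3.0 * std::log(1.0 + p.Vw / V_lv);
  a.P_rv = a.g * p.E_rv * (V_rv - p.V_rv0) + (V_rv - p.V_rv0) / p.C_rv;
  a.P_sa = (V_sa - p.V0_sa) / p.C_sa;
  a.P_sv = (V_sv - p.V0_sv) / p.C_sv;
  a.P_pa = (V_pa - p.V0_pa) / p.C_pa;
  a.P_pv = (V_pv - p.V0_pv) / p.C_pv;
  a.q_mit = diode(a.P_pv - a.P_lv, p.R_mit, p.eps_valve);
  a.q_av = diode(a.P_lv - a.P_sa, p.R_av, p.eps_valve);
  a.q_sys = (a.P_sa - a.P_sv) / p.R_sys;
  a.q_tri = diode(a.P_sv - a.P_rv, p.R_tri, p.eps_valve);
  a.q_pv = diode(a.P_rv - a.P_pa, p.R_pvalve, p.eps_valve);
  a.q_pulm = (a.P_pa - a.P_pv) / p.R_pulm;
}

static inline void rhs(double t, const double* y, const BeatPars& p, double* dy) {
  Alg a;
  algebra(t, y, p, a);
  double dV_lv = a.q_mit - a.q_av;
  dy[0] = dV_lv;
  dy[1] = a.q_tri - a.q_pv;
  dy[2] = a.q_av - a.q_sys;
  dy[3] = a.q_sys - a.q_tri;
  dy[4] = a.q_pv - a.q_pulm;
  dy[5] = a.q_pulm - a.q_mit;
  double dlam_dV = a.lam / (3.0 * (y[0] + p.Vw / 3.0));
  double v_inst = -p.l_s0 * dlam_dV * dV_lv;
  dy[6] = (v_inst - y[6]) / p.tau_v;
}

static void rk4_step(double t, double h, double* y, const BeatPars& p) {
  const int n = 7;
  double k1[n], k2[n], k3[n], k4[n], yt[n];
  rhs(t, y, p, k1);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  rhs(t + 0.5 * h, yt, p, k2);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  rhs(t + 0.5 * h, yt, p, k3);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + h * k3[i];
  rhs(t + h, yt, p, k4);
  for (int i = 0; i < n; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
List cr_run_beats(NumericVector y0, List par, double dt, int max_beats,
                  double tol, bool record) {
  BeatPars p = unpack(par);
  double y[7], y_prev[7];
  for (int i = 0; i < 7; ++i) y[i] = y0[i];
  int nstep = (int) std::lround(p.t_beat / dt);
  if (nstep < 10) stop("beat step too large for the beat period");
  double h = p.t_beat / nstep;

  int beats = 0;
  bool converged = false;
  for (beats = 1; beats <= max_beats; ++beats) {
    for (int i = 0; i < 7; ++i) y_prev[i] = y[i];
    for (int s = 0; s < nstep; ++s) rk4_step(s * h, h, y, p);
    double d = 0.0;
    for (int i = 0; i < 6; ++i) {
      double di = std::fabs(y[i] - y_prev[i]);
      if (di > d) d = di;
    }
    if (d < tol) { converged = true; break; }
  }

  List out;
  if (record) {
    int nr = nstep + 1;
    NumericMatrix W(nr, 14);
    double yr[7];
    for (int i = 0; i < 7; ++i) yr[i] = y[i];
    Alg a;
    for (int s = 0; s <= nstep; ++s) {
      double t = (s == nstep) ? p.t_beat - 1e-12 : s * h;
      algebra(t, yr, p, a);
      W(s, 0) = s * h;
      W(s, 1) = yr[0];           // V_lv
      W(s, 2) = a.P_lv;
      W(s, 3) = a.P_sa;
      W(s, 4) = a.P_sv;
      W(s, 5) = a.P_pa;
      W(s, 6) = a.P_pv;
      W(s, 7) = a.P_rv;
      W(s, 8) = a.q_mit;
      W(s, 9) = a.q_av;
      W(s, 10) = a.lam;
      W(s, 11) = a.sig_p;
      W(s, 12) = a.sig_a;
      W(s, 13) = yr[1];          // V_rv
      if (s < nstep) rk4_step(s * h, h, yr, p);
    }
    colnames(W) = CharacterVector::create(
      "t", "V_lv", "P_lv", "P_sa", "P_sv", "P_pa", "P_pv", "P_rv",
      "q_mit", "q_av", "lambda", "sigma_p", "sigma_a", "V_rv");
    // mean segment volumes are not recorded per step; report end-of-beat state
    out["waveform"] = W;
  }
  NumericVector yend(7);
  for (int i = 0; i < 7; ++i) yend[i] = y[i];
  out["state"] = yend;
  out["beats"] = beats > max_beats ? max_beats : beats;
  out["converged"] = converged;
  return out;
}
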