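// Integration core: 41-compartment Purkinje cell model.
//
// Per step (dt = 25 us default):
//   1. synaptic conductances (dual-exponential state pairs, events snap to grid)
//   2. Hodgkin-Huxley gates, exponential Euler at frozen voltage
//   3. 13-state Markov resurgent-Na occupancy, implicit (backward Euler) solve
//   4. backward-Euler cable solve for voltage (tridiagonal, chain topology)
//   5. calcium shells, floating set point y, w/r switches, pump/[Na+]i update
//
// Units: v mV, t ms, conductance densities S/cm2, currents mA/cm2,
// capacitance uF/cm2, concentrations mM, axial resistance MOhm.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static inline double sexp(double x) {
  if (x > 700.0) x = 700.0; else if (x < -700.0) x = -700.0;
  return std::exp(x);
}

// ---------------------------------------------------------------------------
// Somatic gate laws (Khaliq-sourced; tau printed in seconds, returned in ms).
// Steady states are Boltzmann sigmoids 1/(1+exp(.)).
// ---------------------------------------------------------------------------

static void g_kfast_m(double v, double /*ca*/, double &inf, double &tau) {
  inf = 1.0 / (1.0 + sexp(-(v + 24.0) / 15.4));
  double ts = (v < -35.0)
    ? 0.000103 + 0.0149 * sexp(0.035 * v)
    : 0.000129 + 1.0 / (sexp((v + 100.7) / 12.9) + sexp((v - 56.0) / -23.1));
  tau = 1000.0 * ts;
}
static void g_kfast_h(double v, double /*ca*/, double &inf, double &tau) {
  inf = 0.31 + (1.0 - 0.31) / (1.0 + sexp((v + 5.8) / 11.2));
  double ts = (v <= 0.0)
    ? 1.22e-5 + 0.012 * sexp(-std::pow((v + 56.3) / 49.6, 2.0))
    : 0.0012 + 0.0023 * sexp(-0.141 * v);
  tau = 1000.0 * ts;
}
static void g_kmid_m(double v, double /*ca*/, double &inf, double &tau) {
  inf = 1.0 / (1.0 + sexp(-(v + 24.0) / 20.4));
  double ts = (v < -20.0)
    ? 0.000688 + 1.0 / (sexp((v + 64.2) / 6.5) + sexp((v - 141.5) / -34.8))
    : 0.00016 + 0.0008 * sexp(-0.0267 * v);
  tau = 1000.0 * ts;
}
static void g_kslow_m(double v, double /*ca*/, double &inf, double &tau) {
  inf = 1.0 / (1.0 + sexp(-(v + 16.5) / 18.4));
  double ts = 0.000796 +
    1.0 / (sexp((v + 73.2) / 11.7) + sexp((v - 306.7) / -74.2));
  tau = 1000.0 * ts;
}
static void g_caps_m(double v, double /*ca*/, double &inf, double &tau) {
  inf = 1.0 / (1.0 + sexp(-(v + 19.0) / 5.5));
  double ts = (v <= -50.0)
    ? 0.000264 + 0.128 * sexp(0.103 * v)
    : 0.000191 + 0.00376 * sexp(-std::pow((v + 11.9) / 27.8, 2.0));
  tau = 1000.0 * ts;
}
static void g_ihs_m(double v, double /*ca*/, double &inf, double &tau) {
  inf = 1.0 / (1.0 + sexp((v + 90.1) / 9.9));
  double ts = 0.19 + 0.72 * sexp(-std::pow((v + 81.5) / 11.9, 2.0));
  tau = 1000.0 * ts;
}
static void g_bks_m(double v, double /*ca*/, double &inf, double &tau) {
  inf = 1.0 / (1.0 + sexp(-(v + 28.9) / 6.2));
  double ts = 0.000505 +
    1.0 / (sexp((v + 86.4) / 10.1) + sexp((v - 33.3) / -10.0));
  tau = 1000.0 * ts;
}
static void g_bks_h(double v, double /*ca*/, double &inf, double &tau) {
  inf = 0.085 + (1.0 - 0.085) / (1.0 + sexp((v + 32.0) / 5.8));
  double ts = 0.0019 +
    1.0 / (sexp((v + 48.5) / 5.2) + sexp((v - 54.2) / -12.9));
  tau = 1000.0 * ts;
}
// z gate gated by shell [Ca2+] (mM); z_inf = 1/(1 + 0.001/[Ca]), tau = 1 ms.
static void g_bks_z(double /*v*/, double ca, double &inf, double &tau) {
  inf = 1.0 / (1.0 + 0.001 / ca);
  tau = 1.0;
}

// ---------------------------------------------------------------------------
// Dendritic gate laws (Miyasho-sourced alpha/beta per ms; Saraga Ih;
// Moczydlowski-Latorre SK). mt = 3^((T-37)/10) applied via the update factor.
// ---------------------------------------------------------------------------

static void ab_cat_m(double v, double &a, double &b) {
  a = 2.6 / (1.0 + sexp((v + 21.0) / -8.0));
  b = 0.18 / (1.0 + sexp((v + 40.0) / 4.0));
}
static void ab_cat_h(double v, double &a, double &b) {
  a = 0.0025 / (1.0 + sexp((v + 40.0) / 8.0));
  b = 0.19 / (1.0 + sexp((v + 50.0) / -10.0));
}
static void ab_cae_m(double v, double &a, double &b) {
  a = 2.6 / (1.0 + sexp((v + 7.0) / -8.0));
  b = 0.18 / (1.0 + sexp((v + 26.0) / 4.0));
}
static void ab_cae_h(double v, double &a, double &b) {
  a = 0.0025 / (1.0 + sexp((v + 32.0) / 8.0));
  b = 0.19 / (1.0 + sexp((v + 42.0) / -10.0));
}
static void ab_capd_m(double v, double &a, double &b) {
  a = 8.5 / (1.0 + sexp((v - 8.0) / -12.5));
  b = 35.0 / (1.0 + sexp((v + 74.0) / 14.5));
}
static void ab_ka_m(double v, double &a, double &b) {
  a = 1.4 / (1.0 + sexp((v + 27.0) / -12.0));
  b = 0.49 / (1.0 + sexp((v + 30.0) / 4.0));
}
static void ab_ka_h(double v, double &a, double &b) {
  a = 0.00175 / (1.0 + sexp((v + 50.0) / 8.0));
  b = 0.49 / (1.0 + sexp((v + 13.0) / -10.0));
}
static void ab_kd_m(double v, double &a, double &b) {
  a = 8.5 / (1.0 + sexp((v + 17.0) / -12.5));
  b = 35.0 / (1.0 + sexp((v + 99.0) / 14.5));
}
static void ab_kd_h(double v, double &a, double &b) {
  a = 0.0015 / (1.0 + sexp((v + 89.0) / 8.0));
  b = 0.0055 / (1.0 + sexp((v + 83.0) / -8.0));
}
// Delayed rectifier: HH-style vtrap with a series branch at the singularity.
static double vtrap_dr(double v) {
  double x = -(v + 55.0) / 10.0;
  if (std::fabs(x) < 1e-6) return 10.0 * (1.0 - x / 2.0);
  return -(v + 55.0) / (sexp(x) - 1.0);
}
static void ab_dr_m(double v, double &a, double &b) {
  a = 0.1 * vtrap_dr(v);
  b = 0.125 * sexp(-(v + 65.0) / 80.0);
}
static void ab_bkd_m(double v, double &a, double &b) {
  a = 7.5;
  b = 0.11 / sexp((v - 35.0) / 14.9);
}
static void ab_k2_m(double v, double &a, double &b) {
  a = 25.0;
  b = 0.075 / sexp((v + 5.0) / 10.0);
}
// BK/K2 z gates: alpha_z = 1, beta_z = A/(1000*[Ca]) ([Ca] mM), tau_z = 10 ms.
static void ab_bkd_z(double ca, double &a, double &b) {
  a = 1.0; b = 400.0 / (1000.0 * ca);
}
static void ab_k2_z(double ca, double &a, double &b) {
  a = 1.0; b = 20.0 / (1000.0 * ca);
}
// SK (Moczydlowski-Latorre): v in mV (converted to volts inside), ca in mM.
static void ab_sk_m(double v, double ca, double Tc, double F, double Rg,
                    double &a, double &b) {
  double RT = Rg * (Tc + 273.15);
  a = 0.48 / (1.0 + 0.18 * sexp(-2.0 * 0.84 * F * (v * 1e-3) / RT) / ca);
  b = 0.28 / (1.0 + ca / (0.011 * sexp(-2.0 * 1.0 * F * (v * 1e-3) / RT)));
}
// Saraga Ih: tau in ms directly.
static void g_ihd_m(double v, double &inf, double &tau) {
  inf = 1.0 / (1.0 + sexp((v + 84.1) / 10.2));
  tau = 1.0 / (sexp(-17.9 - 0.116 * v) + sexp(-1.84 + 0.09 * v)) + 100.0;
}
// M-type: tau in ms (includes ft = 2.3^((T-36)/10)).
static void g_km_m(double v, double Tc, double &inf, double &tau) {
  double ft = std::pow(2.3, (Tc - 36.0) / 10.0);
  inf = 1.0 / (1.0 + sexp(-(v + 35.0) / 10.0));
  tau = (1000.0 / ft) / (3.3 * (sexp((v + 35.0) / 40.0) + sexp(-(v + 35.0) / 20.0)));
}

// ---------------------------------------------------------------------------
// GHK flux for the somatic P-type Ca current. Fixed [Ca]i = 100 nM,
// [Ca]o = 2 mM, T = 295 K, P = 5e-5 cm/s. Returns mA/cm2.
// ---------------------------------------------------------------------------
static double ghk_ca_(double v, double F, double Rg, double Tk) {
  const double P = 5e-5;          // cm/s
  const double ci = 1e-10;        // mol/cm3 (100 nM)
  const double co = 2e-6;         // mol/cm3 (2 mM)
  const double z = 2.0;
  double u = z * F * (v * 1e-3) / (Rg * Tk);
  double ratio = (std::fabs(u) < 1e-9) ? 1.0 : u / (-std::expm1(-u));
  return 1000.0 * P * z * F * ratio * (ci - co * sexp(-u));
}

// [[Rcpp::export]]
NumericVector cpp_ghk(NumericVector v, double F = 96485.332,
                      double Rg = 8.314462, double Tk = 295.0) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ghk_ca_(v[i], F, Rg, Tk);
  return out;
}

// ---------------------------------------------------------------------------
// Gate-law dispatcher for tests: returns inf and tau (ms; effective tau for
// alpha/beta channels, i.e. 1/((a+b)*mt*scale)) for a named channel gate.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_gate_inf_tau(std::string channel, std::string gate,
                      NumericVector v, double ca = 1e-4, double Tc = 36.0,
                      double F = 96485.332, double Rg = 8.314462,
                      double k_kd = 0.1) {
  int n = v.size();
  NumericVector inf(n), tau(n);
  double mt = std::pow(3.0, (Tc - 37.0) / 10.0);
  for (int i = 0; i < n; ++i) {
    double vi = v[i], I = NA_REAL, T = NA_REAL, a, b;
    if (channel == "k_fast" && gate == "m") g_kfast_m(vi, ca, I, T);
    else if (channel == "k_fast" && gate == "h") g_kfast_h(vi, ca, I, T);
    else if (channel == "k_mid") g_kmid_m(vi, ca, I, T);
    else if (channel == "k_slow") g_kslow_m(vi, ca, I, T);
    else if (channel == "ca_p_s") g_caps_m(vi, ca, I, T);
    else if (channel == "ih_s") g_ihs_m(vi, ca, I, T);
    else if (channel == "bk_s" && gate == "m") g_bks_m(vi, ca, I, T);
    else if (channel == "bk_s" && gate == "h") g_bks_h(vi, ca, I, T);
    else if (channel == "bk_s" && gate == "z") g_bks_z(vi, ca, I, T);
    else if (channel == "ih_d") g_ihd_m(vi, I, T);
    else if (channel == "k_m") g_km_m(vi, Tc, I, T);
    else {
      double scale = 1.0, mtf = mt;
      if (channel == "ca_t" && gate == "m") ab_cat_m(vi, a, b);
      else if (channel == "ca_t" && gate == "h") ab_cat_h(vi, a, b);
      else if (channel == "ca_e" && gate == "m") { ab_cae_m(vi, a, b); scale = 4.0; }
      else if (channel == "ca_e" && gate == "h") { ab_cae_h(vi, a, b); scale = 10.0; }
      else if (channel == "ca_p_d") ab_capd_m(vi, a, b);
      else if (channel == "k_a" && gate == "m") ab_ka_m(vi, a, b);
      else if (channel == "k_a" && gate == "h") ab_ka_h(vi, a, b);
      else if (channel == "k_d" && gate == "m") { ab_kd_m(vi, a, b); scale = 10.0; }
      else if (channel == "k_d" && gate == "h") { ab_kd_h(vi, a, b); scale = k_kd; }
      else if (channel == "k_dr") ab_dr_m(vi, a, b);
      else if (channel == "bk_d" && gate == "m") { ab_bkd_m(vi, a, b); mtf = 1.0; }
      else if (channel == "bk_d" && gate == "z") { ab_bkd_z(ca, a, b); I = a / (a + b); T = 10.0; inf[i] = I; tau[i] = T; continue; }
      else if (channel == "k2" && gate == "m") { ab_k2_m(vi, a, b); mtf = 1.0; }
      else if (channel == "k2" && gate == "z") { ab_k2_z(ca, a, b); I = a / (a + b); T = 10.0; inf[i] = I; tau[i] = T; continue; }
      else if (channel == "sk") { ab_sk_m(vi, ca, Tc, F, Rg, a, b); mtf = 1.0; }
      else stop("unknown channel/gate: " + channel + "/" + gate);
      I = a / (a + b);
      T = 1.0 / ((a + b) * mtf * scale);
    }
    inf[i] = I; tau[i] = T;
  }
  return List::create(_["inf"] = inf, _["tau"] = tau);
}

// ---------------------------------------------------------------------------
// Markov resurgent Na channel: 13 states.
// Index: 0..4 = C1..C5, 5 = O, 6 = OB, 7..12 = I1..I6.
// ---------------------------------------------------------------------------

static const int NM = 13;

static void markov_rates(double v, double *al, double *be, double &ga,
                         double &de, double &eps, double &ze,
                         double &Con, double &Coff, double &Oon, double &Ooff,
                         double &af, double &bf) {
  *al = 150.0 * sexp(v / 20.0);
  *be = 3.0 * sexp(-v / 20.0);
  ga = 150.0; de = 40.0;
  eps = 1.75; ze = 0.03 * sexp(-v / 25.0);
  Con = 0.005; Coff = 0.5; Oon = 0.75; Ooff = 0.005;
  af = std::pow(Oon / Con, 0.25);
  bf = std::pow(Ooff / Coff, 0.25);
}

// Generator Q: Q[i][j] = rate i->j (i != j), diagonal = -row sum.
static void markov_Q(double v, double Q[NM][NM]) {
  double al, be, ga, de, eps, ze, Con, Coff, Oon, Ooff, a, b;
  markov_rates(v, &al, &be, ga, de, eps, ze, Con, Coff, Oon, Ooff, a, b);
  for (int i = 0; i < NM; ++i)
    for (int j = 0; j < NM; ++j) Q[i][j] = 0.0;
  // closed chain C1..C5 (0..4), then C5 -> O (5)
  double fw[5] = {4 * al, 3 * al, 2 * al, al, ga};
  double bw[5] = {be, 2 * be, 3 * be, 4 * be, de};
  for (int i = 0; i < 5; ++i) { Q[i][i + 1] = fw[i]; Q[i + 1][i] = bw[i]; }
  // O <-> OB, O <-> I6
  Q[5][6] = eps; Q[6][5] = ze;
  Q[5][12] = Oon; Q[12][5] = Ooff;
  // rungs Ci <-> Ii (i = 1..5)
  for (int i = 0; i < 5; ++i) {
    Q[i][7 + i] = Con * std::pow(a, i);
    Q[7 + i][i] = Coff * std::pow(b, i);
  }
  // inactivated chain I1..I6 (7..12), scaled by a (forward) and b (backward)
  double fwi[5] = {4 * al * a, 3 * al * a, 2 * al * a, al * a, ga * a};
  double bwi[5] = {be * b, 2 * be * b, 3 * be * b, 4 * be * b, de * b};
  for (int i = 0; i < 5; ++i) { Q[7 + i][8 + i] = fwi[i]; Q[8 + i][7 + i] = bwi[i]; }
  for (int i = 0; i < NM; ++i) {
    double s = 0.0;
    for (int j = 0; j < NM; ++j) if (j != i) s += Q[i][j];
    Q[i][i] = -s;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_markov_Q(double v) {
  double Q[NM][NM];
  markov_Q(v, Q);
  NumericMatrix out(NM, NM);
  for (int i = 0; i < NM; ++i)
    for (int j = 0; j < NM; ++j) out(i, j) = Q[i][j];
  return out;
}

// Solve (I - dt*A) p_new = p_old with A = Q^T (dp/dt = A p), Gaussian
// elimination with partial pivoting on a 13x13 system.
static void markov_step_(double *p, double v, double dt) {
  double Q[NM][NM];
  markov_Q(v, Q);
  double M[NM][NM + 1];
  for (int i = 0; i < NM; ++i) {
    for (int j = 0; j < NM; ++j)
      M[i][j] = (i == j ? 1.0 : 0.0) - dt * Q[j][i];
    M[i][NM] = p[i];
  }
  for (int c = 0; c < NM; ++c) {
    int piv = c;
    for (int r = c + 1; r < NM; ++r)
      if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
    if (piv != c)
      for (int j = c; j <= NM; ++j) std::swap(M[c][j], M[piv][j]);
    double d = M[c][c];
    for (int r = c + 1; r < NM; ++r) {
      double f = M[r][c] / d;
      if (f == 0.0) continue;
      for (int j = c; j <= NM; ++j) M[r][j] -= f * M[c][j];
    }
  }
  for (int i = NM - 1; i >= 0; --i) {
    double s = M[i][NM];
    for (int j = i + 1; j < NM; ++j) s -= M[i][j] * p[j];
    p[i] = s / M[i][i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_markov_step(NumericVector occ, double v, double dt) {
  if (occ.size() != NM) stop("occupancy must have 13 entries");
  double p[NM];
  for (int i = 0; i < NM; ++i) p[i] = occ[i];
  if (dt > 0) markov_step_(p, v, dt);
  NumericVector out(NM);
  for (int i = 0; i < NM; ++i) out[i] = p[i];
  return out;
}

// Random-voltage walk used by the conservation/positivity property test.
// Returns the worst-case |sum-1| and the most negative occupancy seen.
// [[Rcpp::export]]
List cpp_markov_walk(NumericVector occ0, NumericVector v_seq, double dt) {
  double p[NM];
  for (int i = 0; i < NM; ++i) p[i] = occ0[i];
  double worst_sum = 0.0, min_occ = 1.0;
  for (int s = 0; s < v_seq.size(); ++s) {
    markov_step_(p, v_seq[s], dt);
    double sum = 0.0;
    for (int i = 0; i < NM; ++i) { sum += p[i]; if (p[i] < min_occ) min_occ = p[i]; }
    double d = std::fabs(sum - 1.0);
    if (d > worst_sum) worst_sum = d;
  }
  NumericVector pf(NM);
  for (int i = 0; i < NM; ++i) pf[i] = p[i];
  return List::create(_["occ"] = pf, _["max_abs_sum_err"] = worst_sum,
                      _["min_occupancy"] = min_occ);
}

// ---------------------------------------------------------------------------
// Full model state and parameter plumbing
// ---------------------------------------------------------------------------

// soma gate indices
enum { SG_KF_M, SG_KF_H, SG_KM_M, SG_KS_M, SG_CAP_M, SG_IH_M,
       SG_BK_M, SG_BK_H, SG_BK_Z, NSG };
// dendrite gate columns
enum { DG_CAT_M, DG_CAT_H, DG_CAE_M, DG_CAE_H, DG_CAP_M, DG_IH_M,
       DG_KA_M, DG_KA_H, DG_KM_M, DG_KD_M, DG_KD_H, DG_DR_M,
       DG_BK_M, DG_BK_Z, DG_K2_M, DG_K2_Z, DG_SK_M, NDG };

struct Pars {
  int n;
  std::vector<int> zone;            // 0 soma, 1 smooth, 2 spiny
  std::vector<double> area;         // cm2
  std::vector<double> cm;           // uF/cm2
  std::vector<double> diam;         // um
  std::vector<double> cpar;         // coupling coeff to parent (mA/cm2 per mV)
  std::vector<double> cchild;       // coupling coeff to child
  // densities, S/cm2, per compartment
  std::vector<double> d_nar, d_caps, d_kfast, d_kmid, d_kslow, d_bks, d_ihs,
      d_leaks, d_cat, d_cae, d_capd, d_ka, d_kd, d_km, d_dr, d_bkd, d_k2,
      d_ihd, d_leakd;
  double dt, Tc, F, Rg, mt;
  double ek_s, ek_d, ena, el_s, el_d, eh_s, eh_d, eca_d;
  double k_kd;
  // calcium
  double soma_depth, soma_beta, soma_floor, soma_ca_init, soma_influx_coef;
  double sp_kt, sp_kd, sp_taur, sp_y, sp_depth, sp_ca_init;
  double sm_kt, sm_kd, sm_taur, sm_depth, sm_z, sm_f, sm_s;
  double sm_w_thresh, sm_r_thresh;
  double sm_g_fast, sm_taum_fast, sm_g_slow, sm_taum_slow;
  double gsk_off, gsk_on, sm_ca_init;
  // pump
  double pump_density, pump_tau, na_floor, na_init, ena_floor, na_out;
  // synapses
  double cf_g, cf_tau1, cf_tau2, pf_g, pf_tau1, pf_tau2;
  std::vector<int> cf_comps;
  std::vector<double> cf_times;
  std::vector<int> pf_comps;
  std::vector<std::vector<double> > pf_times;
  // bookkeeping
  int monitor_smooth;               // compartment index monitored for Ca spikes
  double spike_thresh, dspike_thresh;
  double v_init;
};

static void fill_pars(List pl, Pars &P) {
  P.n = as<int>(pl["n"]);
  P.zone = as<std::vector<int> >(pl["zone"]);
  P.area = as<std::vector<double> >(pl["area"]);
  P.cm = as<std::vector<double> >(pl["cm"]);
  P.diam = as<std::vector<double> >(pl["diam"]);
  P.cpar = as<std::vector<double> >(pl["cpar"]);
  P.cchild = as<std::vector<double> >(pl["cchild"]);
  List D = pl["dens"];
  P.d_nar = as<std::vector<double> >(D["na_r"]);
  P.d_caps = as<std::vector<double> >(D["ca_p_s"]);
  P.d_kfast = as<std::vector<double> >(D["k_fast"]);
  P.d_kmid = as<std::vector<double> >(D["k_mid"]);
  P.d_kslow = as<std::vector<double> >(D["k_slow"]);
  P.d_bks = as<std::vector<double> >(D["bk_s"]);
  P.d_ihs = as<std::vector<double> >(D["ih_s"]);
  P.d_leaks = as<std::vector<double> >(D["leak_s"]);
  P.d_cat = as<std::vector<double> >(D["ca_t"]);
  P.d_cae = as<std::vector<double> >(D["ca_e"]);
  P.d_capd = as<std::vector<double> >(D["ca_p_d"]);
  P.d_ka = as<std::vector<double> >(D["k_a"]);
  P.d_kd = as<std::vector<double> >(D["k_d"]);
  P.d_km = as<std::vector<double> >(D["k_m"]);
  P.d_dr = as<std::vector<double> >(D["k_dr"]);
  P.d_bkd = as<std::vector<double> >(D["bk_d"]);
  P.d_k2 = as<std::vector<double> >(D["k2"]);
  P.d_ihd = as<std::vector<double> >(D["ih_d"]);
  P.d_leakd = as<std::vector<double> >(D["leak_d"]);
  P.dt = as<double>(pl["dt"]);
  P.Tc = as<double>(pl["T"]);
  P.F = as<double>(pl["F"]);
  P.Rg = as<double>(pl["Rgas"]);
  P.mt = std::pow(3.0, (P.Tc - 37.0) / 10.0);
  P.ek_s = as<double>(pl["ek_soma"]); P.ek_d = as<double>(pl["ek_dend"]);
  P.ena = as<double>(pl["ena"]);
  P.el_s = as<double>(pl["el_soma"]); P.el_d = as<double>(pl["el_dend"]);
  P.eh_s = as<double>(pl["eh_soma"]); P.eh_d = as<double>(pl["eh_dend"]);
  P.eca_d = as<double>(pl["eca_dend"]);
  P.k_kd = as<double>(pl["k_kd"]);
  List Ca = pl["calcium"];
  P.soma_depth = as<double>(Ca["soma_depth"]);
  P.soma_beta = as<double>(Ca["soma_beta"]);
  P.soma_floor = as<double>(Ca["soma_floor"]);
  P.soma_ca_init = as<double>(Ca["soma_ca_init"]);
  P.soma_influx_coef = as<double>(Ca["soma_influx_coef"]);
  P.sp_kt = as<double>(Ca["spiny_kt"]); P.sp_kd = as<double>(Ca["spiny_kd"]);
  P.sp_taur = as<double>(Ca["spiny_tau_r"]); P.sp_y = as<double>(Ca["spiny_y"]);
  P.sp_depth = as<double>(Ca["spiny_depth"]);
  P.sp_ca_init = as<double>(Ca["spiny_ca_init"]);
  P.sm_kt = as<double>(Ca["smooth_kt"]); P.sm_kd = as<double>(Ca["smooth_kd"]);
  P.sm_taur = as<double>(Ca["smooth_tau_r"]);
  P.sm_depth = as<double>(Ca["smooth_depth"]);
  P.sm_z = as<double>(Ca["smooth_z"]);
  P.sm_f = as<double>(Ca["f"]); P.sm_s = as<double>(Ca["s"]);
  P.sm_w_thresh = as<double>(Ca["w_threshold"]);
  P.sm_r_thresh = as<double>(Ca["r_threshold"]);
  P.sm_g_fast = as<double>(Ca["g_fast"]);
  P.sm_taum_fast = as<double>(Ca["tau_m_fast"]);
  P.sm_g_slow = as<double>(Ca["g_slow"]);
  P.sm_taum_slow = as<double>(Ca["tau_m_slow"]);
  P.gsk_off = as<double>(Ca["gsk_off"]);
  P.gsk_on = as<double>(Ca["gsk_on"]);
  P.sm_ca_init = as<double>(Ca["smooth_ca_init"]);
  List Pu = pl["pump"];
  P.pump_density = as<double>(Pu["density"]);
  P.pump_tau = as<double>(Pu["tau"]);
  P.na_floor = as<double>(Pu["na_floor"]);
  P.na_init = as<double>(Pu["na_init"]);
  P.ena_floor = as<double>(Pu["ena_floor"]);
  P.na_out = as<double>(Pu["na_out"]);
  List Sy = pl["synapses"];
  P.cf_g = as<double>(Sy["cf_g"]);
  P.cf_tau1 = as<double>(Sy["cf_tau1"]); P.cf_tau2 = as<double>(Sy["cf_tau2"]);
  P.pf_g = as<double>(Sy["pf_g"]);
  P.pf_tau1 = as<double>(Sy["pf_tau1"]); P.pf_tau2 = as<double>(Sy["pf_tau2"]);
  P.cf_comps = as<std::vector<int> >(Sy["cf_comps"]);
  P.cf_times = as<std::vector<double> >(Sy["cf_times"]);
  P.pf_comps = as<std::vector<int> >(Sy["pf_comps"]);
  List pft = Sy["pf_times"];
  P.pf_times.clear();
  for (int i = 0; i < pft.size(); ++i)
    P.pf_times.push_back(as<std::vector<double> >(pft[i]));
  P.monitor_smooth = as<int>(pl["monitor_smooth"]);
  P.spike_thresh = as<double>(pl["spike_thresh"]);
  P.dspike_thresh = as<double>(pl["dspike_thresh"]);
  P.v_init = as<double>(pl["v_init"]);
}

static double dualexp_norm(double tau1, double tau2) {
  double tp = tau1 * tau2 / (tau2 - tau1) * std::log(tau2 / tau1);
  return 1.0 / (std::exp(-tp / tau2) - std::exp(-tp / tau1));
}

// [[Rcpp::export]]
List cpp_init_state(List pl) {
  Pars P; fill_pars(pl, P);
  int n = P.n;
  NumericVector v(n, P.v_init);
  NumericVector sg(NSG);
  double inf, tau;
  g_kfast_m(P.v_init, 0, inf, tau); sg[SG_KF_M] = inf;
  g_kfast_h(P.v_init, 0, inf, tau); sg[SG_KF_H] = inf;
  g_kmid_m(P.v_init, 0, inf, tau); sg[SG_KM_M] = inf;
  g_kslow_m(P.v_init, 0, inf, tau); sg[SG_KS_M] = inf;
  g_caps_m(P.v_init, 0, inf, tau); sg[SG_CAP_M] = inf;
  g_ihs_m(P.v_init, 0, inf, tau); sg[SG_IH_M] = inf;
  g_bks_m(P.v_init, 0, inf, tau); sg[SG_BK_M] = inf;
  g_bks_h(P.v_init, 0, inf, tau); sg[SG_BK_H] = inf;
  g_bks_z(P.v_init, P.soma_ca_init > P.soma_floor ? P.soma_ca_init : P.soma_floor,
          inf, tau); sg[SG_BK_Z] = inf;
  NumericMatrix dg(n, NDG);
  for (int i = 0; i < n; ++i) {
    if (P.zone[i] == 0) continue;
    double a, b, ca0 = (P.zone[i] == 1) ? P.sm_ca_init : P.sp_ca_init;
    ab_cat_m(P.v_init, a, b); dg(i, DG_CAT_M) = a / (a + b);
    ab_cat_h(P.v_init, a, b); dg(i, DG_CAT_H) = a / (a + b);
    ab_cae_m(P.v_init, a, b); dg(i, DG_CAE_M) = a / (a + b);
    ab_cae_h(P.v_init, a, b); dg(i, DG_CAE_H) = a / (a + b);
    ab_capd_m(P.v_init, a, b); dg(i, DG_CAP_M) = a / (a + b);
    g_ihd_m(P.v_init, inf, tau); dg(i, DG_IH_M) = inf;
    ab_ka_m(P.v_init, a, b); dg(i, DG_KA_M) = a / (a + b);
    ab_ka_h(P.v_init, a, b); dg(i, DG_KA_H) = a / (a + b);
    g_km_m(P.v_init, P.Tc, inf, tau); dg(i, DG_KM_M) = inf;
    ab_kd_m(P.v_init, a, b); dg(i, DG_KD_M) = a / (a + b);
    ab_kd_h(P.v_init, a, b); dg(i, DG_KD_H) = a / (a + b);
    ab_dr_m(P.v_init, a, b); dg(i, DG_DR_M) = a / (a + b);
    ab_bkd_m(P.v_init, a, b); dg(i, DG_BK_M) = a / (a + b);
    ab_bkd_z(ca0, a, b); dg(i, DG_BK_Z) = a / (a + b);
    ab_k2_m(P.v_init, a, b); dg(i, DG_K2_M) = a / (a + b);
    ab_k2_z(ca0, a, b); dg(i, DG_K2_Z) = a / (a + b);
    ab_sk_m(P.v_init, ca0, P.Tc, P.F, P.Rg, a, b); dg(i, DG_SK_M) = a / (a + b);
  }
  NumericVector occ(NM); occ[0] = 1.0;   // all mass in C1 at rest
  NumericVector ca(n);
  for (int i = 0; i < n; ++i)
    ca[i] = (P.zone[i] == 0) ? P.soma_ca_init
          : (P.zone[i] == 1) ? P.sm_ca_init : P.sp_ca_init;
  NumericVector y(n, P.sm_z), w(n, 0.0), r(n, 0.0);
  int blen = (int)std::lround(P.pump_tau / P.dt);
  NumericVector ring(blen, 0.0);
  int ncf = P.cf_comps.size(), npf = P.pf_comps.size();
  return List::create(
    _["v"] = v, _["soma_gates"] = sg, _["dend_gates"] = dg,
    _["markov"] = occ, _["ca"] = ca, _["y"] = y, _["w"] = w, _["r"] = r,
    _["na_i"] = P.na_init, _["ring"] = ring, _["ring_pos"] = 0,
    _["ring_primed"] = 0,
    _["cfA"] = NumericVector(ncf), _["cfB"] = NumericVector(ncf),
    _["pfA"] = NumericVector(npf), _["pfB"] = NumericVector(npf),
    _["cf_idx"] = 0, _["pf_idx"] = IntegerVector(npf),
    _["t"] = 0.0);
}

// [[Rcpp::export]]
List cpp_run(List pl, List st, int n_steps, int settle_steps = 0,
             int record_stride = 40, int check_stride = 400,
             bool record_all_v = false) {
  Pars P; fill_pars(pl, P);
  const int n = P.n;
  const double dt = P.dt;

  // --- unpack state (copied; inputs untouched) ---
  std::vector<double> v = as<std::vector<double> >(st["v"]);
  std::vector<double> sg = as<std::vector<double> >(st["soma_gates"]);
  NumericMatrix dg0 = st["dend_gates"];
  std::vector<double> dg(n * NDG);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < NDG; ++j) dg[i * NDG + j] = dg0(i, j);
  double occ[NM];
  {
    NumericVector o = st["markov"];
    for (int i = 0; i < NM; ++i) occ[i] = o[i];
  }
  std::vector<double> ca = as<std::vector<double> >(st["ca"]);
  std::vector<double> y = as<std::vector<double> >(st["y"]);
  std::vector<double> w = as<std::vector<double> >(st["w"]);
  std::vector<double> r = as<std::vector<double> >(st["r"]);
  double na_i = as<double>(st["na_i"]);
  std::vector<double> ring = as<std::vector<double> >(st["ring"]);
  int ring_pos = as<int>(st["ring_pos"]);
  int ring_primed = as<int>(st["ring_primed"]);
  std::vector<double> cfA = as<std::vector<double> >(st["cfA"]);
  std::vector<double> cfB = as<std::vector<double> >(st["cfB"]);
  std::vector<double> pfA = as<std::vector<double> >(st["pfA"]);
  std::vector<double> pfB = as<std::vector<double> >(st["pfB"]);
  int cf_idx = as<int>(st["cf_idx"]);
  std::vector<int> pf_idx = as<std::vector<int> >(st["pf_idx"]);
  double t0 = as<double>(st["t"]);

  const int blen = (int)ring.size();
  const double mt = P.mt;
  const double cf_norm = dualexp_norm(P.cf_tau1, P.cf_tau2);
  const double pf_norm = dualexp_norm(P.pf_tau1, P.pf_tau2);
  const double cf_d1 = std::exp(-dt / P.cf_tau1), cf_d2 = std::exp(-dt / P.cf_tau2);
  const double pf_d1 = std::exp(-dt / P.pf_tau1), pf_d2 = std::exp(-dt / P.pf_tau2);
  const int ncf = (int)cfA.size(), npf = (int)pfA.size();
  // unit factor: mM/ms per (mA/cm2) for a 0.1 um (depth in um) shell
  const double sh_soma = P.soma_influx_coef;
  const double sh_sp = 1e4 / (2.0 * P.F * P.sp_depth);
  const double sh_sm = 1e4 / (2.0 * P.F * P.sm_depth);
  const double na_coef = 4e4 / (P.diam[0] * P.F);
  const double Tk295 = 295.0;

  // recording buffers
  int nrec = (n_steps > 0 && record_stride > 0) ? n_steps / record_stride : 0;
  int mon = P.monitor_smooth;
  int nvc = record_all_v ? n : 3;
  NumericMatrix rec_v(nrec, nvc);
  NumericVector rec_t(nrec);
  NumericMatrix rec_sm(nrec, 7);  // ca, y, w, r, gsk, na_i, i_pump
  int rec_i = 0;
  std::vector<double> spikes, dspikes;
  double last_cross = -1e9, last_dcross = -1e9;
  long clamp_ca = 0, clamp_na = 0;

  // work arrays
  std::vector<double> G(n), B(n), Ic(n), gcf(n), gpf(n);
  std::vector<double> al_(n), bl_(n), cl_(n), rl_(n);  // tridiag
  // spiny compartment index for default record (first spiny or last comp)
  int spy = n - 1;
  for (int i = 0; i < n; ++i) if (P.zone[i] == 2) { spy = i; break; }

  const int total_steps = settle_steps + n_steps;
  for (int step = 0; step < total_steps; ++step) {
    bool in_protocol = step >= settle_steps;
    double tp = in_protocol ? t0 + (step - settle_steps) * dt : -1.0;

    // ---- 1. synapses ----
    for (int s = 0; s < ncf; ++s) { cfA[s] *= cf_d1; cfB[s] *= cf_d2; }
    for (int s = 0; s < npf; ++s) { pfA[s] *= pf_d1; pfB[s] *= pf_d2; }
    if (in_protocol) {
      while (cf_idx < (int)P.cf_times.size() &&
             P.cf_times[cf_idx] <= tp + 1e-9) {
        for (int s = 0; s < ncf; ++s) { cfA[s] += 1.0; cfB[s] += 1.0; }
        ++cf_idx;
      }
      for (int s = 0; s < npf; ++s) {
        const std::vector<double> &tt = P.pf_times[s];
        while (pf_idx[s] < (int)tt.size() && tt[pf_idx[s]] <= tp + 1e-9) {
          pfA[s] += 1.0; pfB[s] += 1.0; ++pf_idx[s];
        }
      }
    }
    std::fill(gcf.begin(), gcf.end(), 0.0);
    std::fill(gpf.begin(), gpf.end(), 0.0);
    for (int s = 0; s < ncf; ++s)
      gcf[P.cf_comps[s]] += P.cf_g * cf_norm * (cfB[s] - cfA[s]);  // uS
    for (int s = 0; s < npf; ++s)
      gpf[P.pf_comps[s]] += P.pf_g * pf_norm * (pfB[s] - pfA[s]);

    // ---- 2. gates (exponential Euler at frozen v) ----
    {
      double inf, tau, a, b;
      double vs = v[0];
      g_kfast_m(vs, 0, inf, tau); sg[SG_KF_M] += (inf - sg[SG_KF_M]) * (1.0 - std::exp(-dt / tau));
      g_kfast_h(vs, 0, inf, tau); sg[SG_KF_H] += (inf - sg[SG_KF_H]) * (1.0 - std::exp(-dt / tau));
      g_kmid_m(vs, 0, inf, tau); sg[SG_KM_M] += (inf - sg[SG_KM_M]) * (1.0 - std::exp(-dt / tau));
      g_kslow_m(vs, 0, inf, tau); sg[SG_KS_M] += (inf - sg[SG_KS_M]) * (1.0 - std::exp(-dt / tau));
      g_caps_m(vs, 0, inf, tau); sg[SG_CAP_M] += (inf - sg[SG_CAP_M]) * (1.0 - std::exp(-dt / tau));
      g_ihs_m(vs, 0, inf, tau); sg[SG_IH_M] += (inf - sg[SG_IH_M]) * (1.0 - std::exp(-dt / tau));
      g_bks_m(vs, 0, inf, tau); sg[SG_BK_M] += (inf - sg[SG_BK_M]) * (1.0 - std::exp(-dt / tau));
      g_bks_h(vs, 0, inf, tau); sg[SG_BK_H] += (inf - sg[SG_BK_H]) * (1.0 - std::exp(-dt / tau));
      g_bks_z(vs, ca[0], inf, tau); sg[SG_BK_Z] += (inf - sg[SG_BK_Z]) * (1.0 - std::exp(-dt / tau));
      for (int i = 1; i < n; ++i) {
        double vi = v[i], cai = ca[i];
        double *g = &dg[i * NDG];
        ab_cat_m(vi, a, b); g[DG_CAT_M] += (a / (a + b) - g[DG_CAT_M]) * (1.0 - std::exp(-dt * mt * (a + b)));
        ab_cat_h(vi, a, b); g[DG_CAT_H] += (a / (a + b) - g[DG_CAT_H]) * (1.0 - std::exp(-dt * mt * (a + b)));
        ab_cae_m(vi, a, b); g[DG_CAE_M] += (a / (a + b) - g[DG_CAE_M]) * (1.0 - std::exp(-dt * mt * (a + b) * 4.0));
        ab_cae_h(vi, a, b); g[DG_CAE_H] += (a / (a + b) - g[DG_CAE_H]) * (1.0 - std::exp(-dt * mt * (a + b) * 10.0));
        ab_capd_m(vi, a, b); g[DG_CAP_M] += (a / (a + b) - g[DG_CAP_M]) * (1.0 - std::exp(-dt * mt * (a + b)));
        g_ihd_m(vi, inf, tau); g[DG_IH_M] += (inf - g[DG_IH_M]) * (1.0 - std::exp(-dt / tau));
        ab_ka_m(vi, a, b); g[DG_KA_M] += (a / (a + b) - g[DG_KA_M]) * (1.0 - std::exp(-dt * mt * (a + b)));
        ab_ka_h(vi, a, b); g[DG_KA_H] += (a / (a + b) - g[DG_KA_H]) * (1.0 - std::exp(-dt * mt * (a + b)));
        g_km_m(vi, P.Tc, inf, tau); g[DG_KM_M] += (inf - g[DG_KM_M]) * (1.0 - std::exp(-dt / tau));
        ab_kd_m(vi, a, b); g[DG_KD_M] += (a / (a + b) - g[DG_KD_M]) * (1.0 - std::exp(-dt * mt * (a + b) * 10.0));
        ab_kd_h(vi, a, b); g[DG_KD_H] += (a / (a + b) - g[DG_KD_H]) * (1.0 - std::exp(-dt * mt * (a + b) * P.k_kd));
        ab_dr_m(vi, a, b); g[DG_DR_M] += (a / (a + b) - g[DG_DR_M]) * (1.0 - std::exp(-dt * mt * (a + b)));
        ab_bkd_m(vi, a, b); g[DG_BK_M] += (a / (a + b) - g[DG_BK_M]) * (1.0 - std::exp(-dt * (a + b)));
        ab_bkd_z(cai, a, b); g[DG_BK_Z] += (a / (a + b) - g[DG_BK_Z]) * (1.0 - std::exp(-dt / 10.0));
        ab_k2_m(vi, a, b); g[DG_K2_M] += (a / (a + b) - g[DG_K2_M]) * (1.0 - std::exp(-dt * (a + b)));
        ab_k2_z(cai, a, b); g[DG_K2_Z] += (a / (a + b) - g[DG_K2_Z]) * (1.0 - std::exp(-dt / 10.0));
        ab_sk_m(vi, cai, P.Tc, P.F, P.Rg, a, b);
        g[DG_SK_M] += (a / (a + b) - g[DG_SK_M]) * (1.0 - std::exp(-dt * (a + b)));
      }
    }

    // ---- 3. Markov occupancy, implicit at frozen v ----
    markov_step_(occ, v[0], dt);

    // ---- 4. assemble conductances and backward-Euler cable solve ----
    // membrane eq: (cm*1e-3/dt)(v' - v) = -(G v' - B) - Ic + axial(v')
    for (int i = 0; i < n; ++i) {
      double Gi = 0.0, Bi = 0.0, Ici = 0.0;
      double gsyn = (gcf[i] + gpf[i]) * 1e-6 / P.area[i];  // S/cm2, Erev 0
      Gi += gsyn;
      if (P.zone[i] == 0) {
        double gk;
        gk = P.d_kfast[i] * sg[SG_KF_M] * sg[SG_KF_M] * sg[SG_KF_M] * sg[SG_KF_H];
        Gi += gk; Bi += gk * P.ek_s;
        gk = P.d_kmid[i] * std::pow(sg[SG_KM_M], 4.0);
        Gi += gk; Bi += gk * P.ek_s;
        gk = P.d_kslow[i] * std::pow(sg[SG_KS_M], 4.0);
        Gi += gk; Bi += gk * P.ek_s;
        gk = P.d_bks[i] * std::pow(sg[SG_BK_M], 3.0) * sg[SG_BK_Z] * sg[SG_BK_Z] * sg[SG_BK_H];
        Gi += gk; Bi += gk * P.ek_s;
        gk = P.d_ihs[i] * sg[SG_IH_M];
        Gi += gk; Bi += gk * P.eh_s;
        gk = P.d_leaks[i];
        Gi += gk; Bi += gk * P.el_s;
        gk = P.d_nar[i] * occ[5];
        Gi += gk; Bi += gk * P.ena;
        // GHK P-type: explicit constant at current v (small current)
        Ici += P.d_caps[i] * 1000.0 * sg[SG_CAP_M] * ghk_ca_(v[i], P.F, P.Rg, Tk295);
        // electrogenic pump (net outward)
        Ici += P.pump_density / (1.0 + sexp((40.0 - na_i) / 1.0));
      } else {
        const double *g = &dg[i * NDG];
        double gk;
        gk = P.d_cat[i] * g[DG_CAT_M] * g[DG_CAT_H];
        Gi += gk; Bi += gk * P.eca_d;
        gk = P.d_cae[i] * g[DG_CAE_M] * g[DG_CAE_H];
        Gi += gk; Bi += gk * P.eca_d;
        gk = P.d_capd[i] * g[DG_CAP_M];
        Gi += gk; Bi += gk * P.eca_d;
        gk = P.d_ihd[i] * g[DG_IH_M];
        Gi += gk; Bi += gk * P.eh_d;
        gk = P.d_ka[i] * std::pow(g[DG_KA_M], 4.0) * g[DG_KA_H];
        Gi += gk; Bi += gk * P.ek_d;
        gk = P.d_km[i] * g[DG_KM_M];
        Gi += gk; Bi += gk * P.ek_d;
        gk = P.d_kd[i] * g[DG_KD_M] * g[DG_KD_H];
        Gi += gk; Bi += gk * P.ek_d;
        gk = P.d_dr[i] * std::pow(g[DG_DR_M], 4.0);
        Gi += gk; Bi += gk * P.ek_d;
        gk = P.d_bkd[i] * g[DG_BK_M] * g[DG_BK_Z] * g[DG_BK_Z];
        Gi += gk; Bi += gk * P.ek_d;
        gk = P.d_k2[i] * g[DG_K2_M] * g[DG_K2_Z] * g[DG_K2_Z];
        Gi += gk; Bi += gk * P.ek_d;
        gk = P.d_leakd[i];
        Gi += gk; Bi += gk * P.el_d;
        if (P.zone[i] == 1) {
          double gsk = (r[i] > 0.1 ? P.gsk_on : P.gsk_off) * dg[i * NDG + DG_SK_M];
          Gi += gsk; Bi += gsk * P.ek_d;
        }
      }
      G[i] = Gi; B[i] = Bi; Ic[i] = Ici;
    }
    // tridiagonal assembly (chain: parent of i is i-1)
    for (int i = 0; i < n; ++i) {
      double cap = P.cm[i] * 1e-3 / dt;
      double diag = cap + G[i];
      double rhs = cap * v[i] + B[i] - Ic[i];
      double lo = 0.0, up = 0.0;
      if (i > 0) { lo = -P.cpar[i]; diag += P.cpar[i]; }
      if (i < n - 1) { up = -P.cchild[i]; diag += P.cchild[i]; }
      al_[i] = lo; bl_[i] = diag; cl_[i] = up; rl_[i] = rhs;
    }
    for (int i = 1; i < n; ++i) {   // Thomas
      double f = al_[i] / bl_[i - 1];
      bl_[i] -= f * cl_[i - 1];
      rl_[i] -= f * rl_[i - 1];
    }
    std::vector<double> vnew(n);
    vnew[n - 1] = rl_[n - 1] / bl_[n - 1];
    for (int i = n - 2; i >= 0; --i)
      vnew[i] = (rl_[i] - cl_[i] * vnew[i + 1]) / bl_[i];

    // spike detection at full rate (soma upward crossing; dendritic Ca spike
    // on the monitored smooth compartment)
    if (in_protocol) {
      if (v[0] < P.spike_thresh && vnew[0] >= P.spike_thresh &&
          tp - last_cross > 1.0) { spikes.push_back(tp); last_cross = tp; }
      if (v[mon] < P.dspike_thresh && vnew[mon] >= P.dspike_thresh &&
          tp - last_dcross > 2.0) { dspikes.push_back(tp); last_dcross = tp; }
    }

    // ---- 5. calcium / switches / pump at the new voltage ----
    double i_pump = P.pump_density / (1.0 + sexp((40.0 - na_i) / 1.0));
    double i_nar = P.d_nar[0] * occ[5] * (vnew[0] - P.ena);
    // soma shell
    {
      double i_cap = P.d_caps[0] * 1000.0 * sg[SG_CAP_M] * ghk_ca_(vnew[0], P.F, P.Rg, Tk295);
      double cnew = ca[0] + dt * (-sh_soma * i_cap - P.soma_beta * ca[0]);
      if (cnew < P.soma_floor) { cnew = P.soma_floor; ++clamp_ca; }
      ca[0] = cnew;
    }
    for (int i = 1; i < n; ++i) {
      const double *g = &dg[i * NDG];
      double ica = (P.d_cat[i] * g[DG_CAT_M] * g[DG_CAT_H] +
                    P.d_cae[i] * g[DG_CAE_M] * g[DG_CAE_H] +
                    P.d_capd[i] * g[DG_CAP_M]) * (vnew[i] - P.eca_d);
      double chan_in = (ica < 0.0) ? -ica : 0.0;  // clamped influx magnitude
      if (P.zone[i] == 2) {
        double chan = sh_sp * chan_in;
        ca[i] += dt * (chan - P.sp_kt * ca[i] / (ca[i] + P.sp_kd) +
                       (P.sp_y - ca[i]) / P.sp_taur);
        if (ca[i] < 1e-12) ca[i] = 1e-12;
      } else if (P.zone[i] == 1) {
        double chan = sh_sm * chan_in;
        ca[i] += dt * (chan - P.sm_kt * ca[i] / (ca[i] + P.sm_kd) +
                       (y[i] - ca[i]) / P.sm_taur);
        if (ca[i] < 1e-12) ca[i] = 1e-12;
        // w switch: large inward Ca current marks a CF-scale influx
        if (chan_in > P.sm_w_thresh) w[i] = 1.0;
        else w[i] *= std::exp(-dt / P.sm_f);
        double gy = (w[i] > 0.1) ? P.sm_g_slow : P.sm_g_fast;
        double taum = (w[i] > 0.1) ? P.sm_taum_slow : P.sm_taum_fast;
        y[i] += dt * (4e4 * chan_in / (P.diam[i] * P.F * gy) +
                      (P.sm_z - y[i]) / taum);
        if (y[i] < 1e-12) y[i] = 1e-12;
        // r switch: CF synaptic current magnitude (nA) above threshold
        double icf = std::fabs(gcf[i] * vnew[i]);  // uS * mV = nA
        if (icf > P.sm_r_thresh) r[i] = 1.0;
        else r[i] *= std::exp(-dt / P.sm_s);
      }
    }
    // pump / lagged [Na+]i
    {
      // net outward Na+ current: resurgent influx (negative) plus pump
      // efflux (3 i_pump, positive); [Na+]i integrates its negative
      double push = i_nar + 3.0 * i_pump;
      if (!ring_primed) { std::fill(ring.begin(), ring.end(), push); ring_primed = 1; }
      double inet = ring[ring_pos];
      ring[ring_pos] = push;
      ring_pos = (ring_pos + 1) % blen;
      na_i += dt * (-na_coef * inet);
      if (na_i < P.na_floor) { na_i = P.na_floor; ++clamp_na; }
    }

    for (int i = 0; i < n; ++i) v[i] = vnew[i];

    // ---- state validity checks ----
    if (check_stride > 0 && step % check_stride == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(v[i]))
          stop("integration failure: non-finite voltage in compartment %d at t=%f ms", i, tp);
      double s = 0.0;
      for (int q = 0; q < NM; ++q) {
        s += occ[q];
        if (occ[q] < -1e-9 || occ[q] > 1.0 + 1e-9)
          stop("integration failure: Markov occupancy out of range");
      }
      if (std::fabs(s - 1.0) > 1e-9)
        stop("integration failure: Markov occupancy sum drift");
      for (int q = 0; q < NSG; ++q)
        if (sg[q] < -1e-9 || sg[q] > 1.0 + 1e-9)
          stop("integration failure: soma gate out of [0,1]");
      if (na_i < P.na_floor - 1e-9) stop("integration failure: [Na+]i below floor");
    }

    // ---- recording ----
    if (in_protocol && record_stride > 0) {
      int ps = step - settle_steps;
      if ((ps + 1) % record_stride == 0 && rec_i < nrec) {
        rec_t[rec_i] = tp;
        if (record_all_v) {
          for (int i = 0; i < n; ++i) rec_v(rec_i, i) = v[i];
        } else {
          rec_v(rec_i, 0) = v[0];
          rec_v(rec_i, 1) = v[mon];
          rec_v(rec_i, 2) = v[spy];
        }
        rec_sm(rec_i, 0) = ca[mon];
        rec_sm(rec_i, 1) = y[mon];
        rec_sm(rec_i, 2) = w[mon];
        rec_sm(rec_i, 3) = r[mon];
        rec_sm(rec_i, 4) = (r[mon] > 0.1 ? P.gsk_on : P.gsk_off);
        rec_sm(rec_i, 5) = na_i;
        rec_sm(rec_i, 6) = i_pump;
        ++rec_i;
      }
    }
  }

  // ---- pack final state ----
  NumericMatrix dgout(n, NDG);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < NDG; ++j) dgout(i, j) = dg[i * NDG + j];
  NumericVector occv(NM);
  for (int i = 0; i < NM; ++i) occv[i] = occ[i];
  List fin = List::create(
    _["v"] = wrap(v), _["soma_gates"] = wrap(sg), _["dend_gates"] = dgout,
    _["markov"] = occv, _["ca"] = wrap(ca), _["y"] = wrap(y),
    _["w"] = wrap(w), _["r"] = wrap(r), _["na_i"] = na_i,
    _["ring"] = wrap(ring), _["ring_pos"] = ring_pos,
    _["ring_primed"] = ring_primed,
    _["cfA"] = wrap(cfA), _["cfB"] = wrap(cfB),
    _["pfA"] = wrap(pfA), _["pfB"] = wrap(pfB),
    _["cf_idx"] = cf_idx, _["pf_idx"] = wrap(pf_idx),
    _["t"] = t0 + n_steps * dt);
  return List::create(
    _["t"] = rec_t, _["v"] = rec_v, _["smooth"] = rec_sm,
    _["spikes"] = wrap(spikes), _["dend_spikes"] = wrap(dspikes),
    _["state"] = fin,
    _["clamp_ca"] = (double)clamp_ca, _["clamp_na"] = (double)clamp_na);
}
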