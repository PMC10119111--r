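// Core fixed-step RK4 integrator for the coupled neuronal-astrocyte-vascular
// ODE system, plus a single-cell AdEx Monte-Carlo used as an independent
// oracle for the mean-field transfer function in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  // neuronal
  double T, tau_w, a, b, C_m, g_L, E_L, E_e, E_i, Q_e, Q_i, tau_e, tau_i;
  double K_e, K_i;                 // in-degrees p*N_e, p*N_i
  double P_e[10], P_i[10];
  double muV0, DmuV0, sV0, DsV0, TvN0, DTvN0;
  double glu_scale, g_r, g_ext;    // glu_scale = p*N_e*Q_e[nS]*tau_e
  // astrocyte
  double C_T, rho_A, Gamma_C, Gamma_L, O_P, K_P, pump_hill, leak_sign;
  double d1, d2, d3, d5, O_2;
  double v_beta, K_R, K_p, K_pi, v_delta, kappa_delta, K_delta;
  double v_3K, K_D, K_3, r_5P;
  double tau_AA, O_AA, K_AA, tau_PG, O_PG, K_PG;
  // vascular
  double tau_R, O_R, tau_cAMP, O_cAMP, cAMP_o, D_A, K_VA, alpha_A;
  // balloon
  double tau_0, tau_v, E_0, alpha_V, V_0, k1, k2, k3;
  // run options
  double ca_clamp;        // cap on Ca as input to AA production
  double glu_floor_time;  // from this time on, nu_e for glutamate >= glu_floor_nu
  double glu_floor_nu;
};

static void fill_poly(NumericVector src, double dst[10]) {
  for (int i = 0; i < 10; ++i) dst[i] = src[i];
}

static Pars unpack(List params, List opts) {
  Pars p;
  List n = params["neuronal"], a = params["astrocyte"],
       v = params["vascular"], b = params["balloon"];
  p.T = n["T"]; p.tau_w = n["tau_w"]; p.a = n["a"]; p.b = n["b"];
  p.C_m = n["C_m"]; p.g_L = n["g_L"]; p.E_L = n["E_L"];
  p.E_e = n["E_e"]; p.E_i = n["E_i"];
  p.Q_e = n["Q_e"]; p.Q_i = n["Q_i"]; p.tau_e = n["tau_e"]; p.tau_i = n["tau_i"];
  double pc = n["p_conn"], Ne = n["N_e"], Ni = n["N_i"];
  p.K_e = pc * Ne; p.K_i = pc * Ni;
  fill_poly(n["P_e"], p.P_e); fill_poly(n["P_i"], p.P_i);
  p.muV0 = n["muV0"]; p.DmuV0 = n["DmuV0"]; p.sV0 = n["sV0"];
  p.DsV0 = n["DsV0"]; p.TvN0 = n["TvN0"]; p.DTvN0 = n["DTvN0"];
  p.glu_scale = pc * Ne * (p.Q_e * 1e9) * p.tau_e;
  p.g_r = n["g_r"]; p.g_ext = n["g_ext"];
  p.C_T = a["C_T"]; p.rho_A = a["rho_A"]; p.Gamma_C = a["Gamma_C"];
  p.Gamma_L = a["Gamma_L"]; p.O_P = a["O_P"]; p.K_P = a["K_P"];
  p.pump_hill = a["pump_hill"]; p.leak_sign = a["leak_sign"];
  p.d1 = a["d1"]; p.d2 = a["d2"]; p.d3 = a["d3"]; p.d5 = a["d5"];
  p.O_2 = a["O_2"];
  p.v_beta = a["v_beta"]; p.K_R = a["K_R"]; p.K_p = a["K_p"]; p.K_pi = a["K_pi"];
  p.v_delta = a["v_delta"]; p.kappa_delta = a["kappa_delta"]; p.K_delta = a["K_delta"];
  p.v_3K = a["v_3K"]; p.K_D = a["K_D"]; p.K_3 = a["K_3"]; p.r_5P = a["r_5P"];
  p.tau_AA = a["tau_AA"]; p.O_AA = a["O_AA"]; p.K_AA = a["K_AA"];
  p.tau_PG = a["tau_PG"]; p.O_PG = a["O_PG"]; p.K_PG = a["K_PG"];
  p.tau_R = v["tau_R"]; p.O_R = v["O_R"]; p.tau_cAMP = v["tau_cAMP"];
  p.O_cAMP = v["O_cAMP"];
  p.cAMP_o = Rf_isNull(v["cAMP_o"]) ? NA_REAL : as<double>(v["cAMP_o"]);
  p.D_A = v["D_A"]; p.K_VA = v["K_VA"]; p.alpha_A = v["alpha_A"];
  p.tau_0 = b["tau_0"]; p.tau_v = b["tau_v"]; p.E_0 = b["E_0"];
  p.alpha_V = b["alpha_V"]; p.V_0 = b["V_0"];
  p.k1 = b["k1"]; p.k2 = b["k2"]; p.k3 = b["k3"];
  p.ca_clamp = opts.containsElementNamed("ca_clamp") ?
    as<double>(opts["ca_clamp"]) : R_PosInf;
  p.glu_floor_time = opts.containsElementNamed("glu_floor_time") ?
    as<double>(opts["glu_floor_time"]) : R_PosInf;
  p.glu_floor_nu = opts.containsElementNamed("glu_floor_nu") ?
    as<double>(opts["glu_floor_nu"]) : 0.0;
  return p;
}

static inline double hillf(double x, double K) { return x / (x + K); }

// semi-analytic AdEx transfer function (erfc rate from membrane moments)
static double transfer_rate(double fe_hz, double fi_hz, double W_pA,
                            const Pars &p, const double P[10]) {
  double fe = (fe_hz + 1e-6) * p.K_e;
  double fi = (fi_hz + 1e-6) * p.K_i;
  double muGe = p.Q_e * p.tau_e * fe;
  double muGi = p.Q_i * p.tau_i * fi;
  double muG = p.g_L + muGe + muGi;
  double muV = (muGe * p.E_e + muGi * p.E_i + p.g_L * p.E_L - W_pA * 1e-12) / muG;
  double Tm = p.C_m / muG;
  double Ue = p.Q_e / muG * (p.E_e - muV);
  double Ui = p.Q_i / muG * (p.E_i - muV);
  double se = fe * (Ue * p.tau_e) * (Ue * p.tau_e);
  double si = fi * (Ui * p.tau_i) * (Ui * p.tau_i);
  double sV = std::sqrt(se / (2 * (p.tau_e + Tm)) + si / (2 * (p.tau_i + Tm)));
  double Tv = (se + si) / (se / (p.tau_e + Tm) + si / (p.tau_i + Tm));
  double TvN = Tv * p.g_L / p.C_m;
  double xm = (muV - p.muV0) / p.DmuV0;
  double xs = (sV - p.sV0) / p.DsV0;
  double xt = (TvN - p.TvN0) / p.DTvN0;
  double Vt = P[0] + P[1] * xm + P[2] * xs + P[3] * xt +
    P[4] * xm * xm + P[5] * xs * xs + P[6] * xt * xt +
    P[7] * xm * xs + P[8] * xm * xt + P[9] * xs * xt;
  // far outside the fitted fluctuation regime (mean voltage pushed to
  // absurdly hyperpolarised values by extreme adaptation) the neuron is
  // silent; the threshold polynomial must not be extrapolated there
  if (muV < -0.2) return 0.0;
  double rate = std::erfc((Vt - muV) / (std::sqrt(2.0) * sV)) / (2 * Tv);
  return rate > 0 ? rate : 0.0;
}

// [[Rcpp::export(name = ".cpp_transfer_rate")]]
double cpp_transfer_rate(double fe_hz, double fi_hz, double W_pA,
                         List params, std::string pop) {
  Pars p = unpack(params, List::create());
  return transfer_rate(fe_hz, fi_hz, W_pA, p,
                       pop == "e" ? p.P_e : p.P_i);
}

// full 12-state RHS; y = (nu_e, nu_i, W, Ca, h, IP3, AA, PG, R_PG, cAMP, v, q)
static void rhs(double t, const double y[12], double nu_ext,
                const Pars &p, double dy[12]) {
  double nu_e = y[0] > 0 ? y[0] : 0.0;
  double nu_i = y[1] > 0 ? y[1] : 0.0;
  double W = y[2];
  double Ca = y[3] > 0 ? y[3] : 0.0;
  double h = y[4] < 0 ? 0.0 : (y[4] > 1 ? 1.0 : y[4]);
  double IP3 = y[5] > 0 ? y[5] : 0.0;
  double AA = y[6] > 0 ? y[6] : 0.0;
  double PG = y[7] > 0 ? y[7] : 0.0;
  double R = y[8] < 0 ? 0.0 : (y[8] > 1 ? 1.0 : y[8]);
  double cAMP = y[9], v = y[10], q = y[11];

  // neuronal
  double nbar = nu_e + nu_ext;
  double Fe = transfer_rate(nbar, nu_i, W, p, p.P_e);
  double Fi = transfer_rate(nbar, nu_i, 0.0, p, p.P_i);
  dy[0] = (Fe - nu_e) / p.T;
  dy[1] = (Fi - nu_i) / p.T;
  dy[2] = -W / p.tau_w + p.b * nu_e;   // a = 0 default; mu_V term added below
  if (p.a != 0) {
    double fe = (nbar + 1e-6) * p.K_e, fi = (nu_i + 1e-6) * p.K_i;
    double muGe = p.Q_e * p.tau_e * fe, muGi = p.Q_i * p.tau_i * fi;
    double muG = p.g_L + muGe + muGi;
    double muV = (muGe * p.E_e + muGi * p.E_i + p.g_L * p.E_L - W * 1e-12) / muG;
    dy[2] += p.a * (muV - p.E_L) * 1e3;  // a[nS] * dV[mV] -> pA
  }

  // glutamate (algebraic), with optional post-offset floor on nu_e
  double nu_e_glu = nu_e;
  if (t >= p.glu_floor_time && nu_e_glu < p.glu_floor_nu)
    nu_e_glu = p.glu_floor_nu;
  double Glu = (p.g_r * nu_e_glu + p.g_ext * nu_ext) * p.glu_scale;

  // astrocyte calcium / IP3
  double m_inf = hillf(IP3, p.d1) * hillf(Ca, p.d5);
  double res_C = p.C_T - (1 + p.rho_A) * Ca;
  double res_L = p.C_T - (1 + p.leak_sign * p.rho_A) * Ca;
  double J_C = p.Gamma_C * m_inf * m_inf * m_inf * h * h * h * res_C;
  double J_L = p.Gamma_L * res_L;
  double J_P = p.O_P * std::pow(Ca, p.pump_hill) /
    (std::pow(Ca, p.pump_hill) + std::pow(p.K_P, p.pump_hill));
  dy[3] = J_C + J_L - J_P;
  double den = p.d2 * (IP3 + p.d1) + (IP3 + p.d3) * Ca;
  double h_inf = p.d2 * (IP3 + p.d1) / den;
  double tau_h = (1 / p.O_2) * (IP3 + p.d3) / den;
  dy[4] = (h_inf - h) / tau_h;
  double K_gamma = p.K_R * (1 + (p.K_p / p.K_R) * hillf(Ca, p.K_pi));
  double J_beta = p.v_beta * std::pow(Glu, 0.7) /
    (std::pow(Glu, 0.7) + std::pow(K_gamma, 0.7));
  double Ca2 = Ca * Ca;
  double J_delta = p.v_delta / (1 + IP3 / p.kappa_delta) *
    Ca2 / (Ca2 + p.K_delta * p.K_delta);
  double Ca4 = Ca2 * Ca2, K_D4 = std::pow(p.K_D, 4);
  double J_3K = p.v_3K * Ca4 / (Ca4 + K_D4) * hillf(IP3, p.K_3);
  dy[5] = J_beta + J_delta - J_3K - p.r_5P * IP3;

  // AA / PG cascade (optionally amplitude-clamped calcium input)
  double Ca_aa = Ca < p.ca_clamp ? Ca : p.ca_clamp;
  dy[6] = -AA / p.tau_AA + p.O_AA * hillf(Ca_aa, p.K_AA);
  dy[7] = -PG / p.tau_PG + p.O_PG * hillf(AA, p.K_PG);

  // receptors, cAMP, arteriole, balloon
  dy[8] = -R / p.tau_R + p.O_R * PG * (1 - R);
  dy[9] = -cAMP / p.tau_cAMP + p.O_cAMP * R;
  double dc = cAMP - p.cAMP_o;
  double CBV_A = 1 + p.D_A * dc / (p.K_VA * p.K_VA + dc * dc);
  double f_in = std::pow(CBV_A, 1.0 / p.alpha_A);
  double f_out_ss = std::pow(v, 1.0 / p.alpha_V);
  double dv = (f_in - f_out_ss) / (p.tau_0 + p.tau_v);
  double f_out = f_out_ss + p.tau_v * dv;
  double E_f = 1 - std::pow(1 - p.E_0, 1.0 / f_in);
  dy[10] = dv;
  dy[11] = (f_in * E_f / p.E_0 - f_out * q / v) / p.tau_0;
}

// The RHS evaluates all bounded quantities (rates, Ca, h, IP3, AA, PG,
// R_PG) through clamped copies, so small negative (or > 1) transients in
// the raw state are self-correcting; clamping the state itself every step
// would reduce the integrator to first order near the bounds. Recorded
// output is clamped instead.
static void clip_output(double y[12]) {
  for (int k = 0; k < 2; ++k) if (y[k] < 0) y[k] = 0;       // rates
  if (y[3] < 0) y[3] = 0;                                   // Ca
  if (y[4] < 0) y[4] = 0; if (y[4] > 1) y[4] = 1;           // h
  if (y[5] < 0) y[5] = 0;                                   // IP3
  if (y[6] < 0) y[6] = 0; if (y[7] < 0) y[7] = 0;           // AA, PG
  if (y[8] < 0) y[8] = 0; if (y[8] > 1) y[8] = 1;           // R_PG
}

// Integrate the coupled system with fixed-step RK4.
// nu_ext_half: external drive sampled on the half-step grid, length 2*n+1.
// Records every `stride` steps (including t = 0); returns a matrix with
// columns t, 12 states, Glu, CBV_A, CBF_in, CBF_out, BOLD(percent).
// [[Rcpp::export(name = ".cpp_run_nvc")]]
NumericMatrix cpp_run_nvc(NumericVector init, NumericVector nu_ext_half,
                          double dt, int stride, List params, List opts) {
  Pars p = unpack(params, opts);
  if (!R_finite(p.cAMP_o))
    stop("cAMP_o must be resolved before integration");
  int n2 = nu_ext_half.size();
  if (n2 < 3 || n2 % 2 == 0)
    stop("nu_ext_half must have odd length 2*n_steps + 1");
  int n_steps = (n2 - 1) / 2;
  int n_rec = n_steps / stride + 1;
  NumericMatrix out(n_rec, 18);
  double y[12], k1[12], k2[12], k3[12], k4[12], tmp[12];
  for (int k = 0; k < 12; ++k) y[k] = init[k];

  int row = 0;
  for (int i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    if (i % stride == 0) {
      // algebraic outputs at the recorded time
      double nu_e_glu = y[0] > 0 ? y[0] : 0;
      if (t >= p.glu_floor_time && nu_e_glu < p.glu_floor_nu)
        nu_e_glu = p.glu_floor_nu;
      double Glu = (p.g_r * nu_e_glu + p.g_ext * nu_ext_half[2 * i]) * p.glu_scale;
      double dc = y[9] - p.cAMP_o;
      double CBV_A = 1 + p.D_A * dc / (p.K_VA * p.K_VA + dc * dc);
      double f_in = std::pow(CBV_A, 1.0 / p.alpha_A);
      double f_out_ss = std::pow(y[10], 1.0 / p.alpha_V);
      double dv = (f_in - f_out_ss) / (p.tau_0 + p.tau_v);
      double f_out = f_out_ss + p.tau_v * dv;
      double bold = p.V_0 * (p.k1 * (1 - y[11]) + p.k2 * (1 - y[11] / y[10]) +
                             p.k3 * (1 - y[10]));
      double yc[12];
      for (int k = 0; k < 12; ++k) yc[k] = y[k];
      clip_output(yc);
      out(row, 0) = t;
      for (int k = 0; k < 12; ++k) out(row, k + 1) = yc[k];
      out(row, 13) = Glu; out(row, 14) = CBV_A; out(row, 15) = f_in;
      out(row, 16) = f_out; out(row, 17) = 100 * bold;
      ++row;
    }
    if (i == n_steps) break;
    // the drive is treated as constant over each step, sampled at the step
    // midpoint: exact for edge-aligned rectangular protocols and far below
    // the integrator error for slow sinusoids; using the raw edge samples
    // in k1/k4 would leak the post-edge value into the preceding step and
    // reduce the scheme to first order at stimulus edges
    double uh = nu_ext_half[2 * i + 1];
    rhs(t, y, uh, p, k1);
    for (int k = 0; k < 12; ++k) tmp[k] = y[k] + dt / 2 * k1[k];
    rhs(t + dt / 2, tmp, uh, p, k2);
    for (int k = 0; k < 12; ++k) tmp[k] = y[k] + dt / 2 * k2[k];
    rhs(t + dt / 2, tmp, uh, p, k3);
    for (int k = 0; k < 12; ++k) tmp[k] = y[k] + dt * k3[k];
    rhs(t + dt, tmp, uh, p, k4);
    for (int k = 0; k < 12; ++k)
      y[k] += dt / 6 * (k1[k] + 2 * k2[k] + 2 * k3[k] + k4[k]);
    for (int k = 0; k < 12; ++k) {
      if (!R_finite(y[k])) {
        const char *nm[12] = {"nu_e", "nu_i", "W", "Ca", "h", "IP3",
                              "AA", "PG", "R_PG", "cAMP", "v", "q"};
        stop("state variable '%s' became non-finite at t = %.4f s",
             nm[k], t + dt);
      }
    }
  }
  return out;
}

// RHS exposed for cross-checking the R-level stage derivatives.
// [[Rcpp::export(name = ".cpp_rhs_nvc")]]
NumericVector cpp_rhs_nvc(NumericVector y_in, double nu_ext, double t,
                          List params, List opts) {
  Pars p = unpack(params, opts);
  double y[12], dy[12];
  for (int k = 0; k < 12; ++k) y[k] = y_in[k];
  rhs(t, y, nu_ext, p, dy);
  NumericVector out(12);
  for (int k = 0; k < 12; ++k) out[k] = dy[k];
  return out;
}

// Single-cell AdEx Monte-Carlo under Poissonian conductance bombardment:
// an independent estimate of the population transfer function. Presynaptic
// rates are per-neuron rates; in-degrees and quantal sizes are taken from
// the parameter registry. Returns the mean firing rate over t_total after
// discarding t_burn.
// [[Rcpp::export(name = ".cpp_adex_mc_rate")]]
double cpp_adex_mc_rate(double nu_e_hz, double nu_i_hz, double W_fixed_pA,
                        List params, double t_total, double t_burn,
                        double dt, int seed, std::string pop) {
  Pars p = unpack(params, List::create());
  // single-cell AdEx constants (regular-spiking / fast-spiking)
  double V_T = -50e-3, Delta = (pop == "e") ? 2e-3 : 0.5e-3;
  double V_r = -65e-3, V_spike = -30e-3, t_ref = 5e-3;
  double lam_e = nu_e_hz * p.K_e * dt;
  double lam_i = nu_i_hz * p.K_i * dt;
  // R's RNG for reproducibility under set.seed at the R level is not used
  // here; a local xorshift keeps the oracle self-contained.
  uint64_t s = (uint64_t)seed * 2654435761u + 1442695040888963407ull;
  auto runif01 = [&]() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return (double)(s >> 11) * (1.0 / 9007199254740992.0);
  };
  auto rpois = [&](double lam) {
    // Knuth; lam is tiny (<< 1) per step
    double L = std::exp(-lam), prod = runif01();
    int k = 0;
    while (prod > L) { ++k; prod *= runif01(); }
    return k;
  };
  double V = p.E_L, ge = 0, gi = 0, w = W_fixed_pA * 1e-12;
  double refr = 0;
  long n_spk = 0;
  long n_steps = (long)((t_total + t_burn) / dt);
  for (long i = 0; i < n_steps; ++i) {
    ge += rpois(lam_e) * p.Q_e;
    gi += rpois(lam_i) * p.Q_i;
    ge -= ge * dt / p.tau_e;
    gi -= gi * dt / p.tau_i;
    if (refr > 0) {
      refr -= dt;
    } else {
      double Iexp = p.g_L * Delta * std::exp((V - V_T) / Delta);
      double dV = (-p.g_L * (V - p.E_L) + Iexp - ge * (V - p.E_e) -
                   gi * (V - p.E_i) - w) / p.C_m;
      V += dt * dV;
      if (V > V_spike) {
        V = V_r; refr = t_ref;
        if (i * dt > t_burn) ++n_spk;
      }
    }
  }
  return n_spk / t_total;
}
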