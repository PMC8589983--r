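#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Current-to-rate transfer of the decision pools; series expansion at the
// removable singularity c_e*I = i_th. Must match phi_decision() in R.
static inline double phi_dec(double i, double c_e, double i_th, double g_e) {
  double u = c_e * i - i_th;
  double z = g_e * u;
  double out;
  if (std::fabs(z) < 1e-8) {
    out = (1.0 + z / 2.0 + z * z / 12.0) / g_e;
  } else {
    out = u / (1.0 - std::exp(-z));
  }
  return out > 0.0 ? out : 0.0;
}

static inline double phi_conf(double i, double c_e, double i_th_c) {
  double v = c_e * i - i_th_c;
  return v > 0.5 ? v : 0.5;
}

struct Pars {
  double tau_nmda, tau_a, tau_r, tau_d, gamma, j_ii, j_ij, j_c, j_fc,
      j_ext, j_dc, j_a_eff, c_e, i_th, g_e, i_th_c, a_1, a_0, mu_0,
      u_0_eff, i_0, i_0c, dt, noise_sigma, noise_tau;
  int variant;      // 0 adaptation, 1 std, 2 none
  int rate_mode;    // 0 relaxation, 1 literal
  int std_site;     // 0 feedforward, 1 recurrent
};

struct Deriv {
  double ds_a, ds_b, ds_c, dr_c, da, dx;
  double r_a, r_b, i_a, i_b, i_c;
};

// Deterministic derivative field with the noise currents frozen.
static inline Deriv field(const Pars &p, double t,
                          double s_a, double s_b, double s_c, double r_c,
                          double a, double x,
                          double in_a, double in_b, double in_c,
                          double stim_on, double stim_off,
                          double ext_a, double ext_b) {
  Deriv d;
  bool on = (t >= stim_on) && (t < stim_off);
  double ia = p.j_ii * s_a - p.j_ij * s_b + p.i_0 + (on ? ext_a : 0.0) +
              p.j_fc * r_c + in_a;
  double ib = p.j_ii * s_b - p.j_ij * s_a + p.i_0 + (on ? ext_b : 0.0) +
              p.j_fc * r_c + in_b;
  double r_a = phi_dec(ia, p.c_e, p.i_th, p.g_e);
  double r_b = phi_dec(ib, p.c_e, p.i_th, p.g_e);
  double r_in = r_a + r_b;

  double ic;
  if (p.variant == 0) { // adaptation
    ic = p.j_c * s_c + p.j_dc * r_in + p.i_0c + in_c - p.j_a_eff * a;
  } else if (p.variant == 1) { // short-term depression
    if (p.std_site == 0)
      ic = p.j_c * s_c + p.j_dc * r_in * x + p.i_0c + in_c;
    else
      ic = p.j_c * s_c * x + p.j_dc * r_in + p.i_0c + in_c;
  } else { // none
    ic = p.j_c * s_c + p.j_dc * r_in + p.i_0c + in_c;
  }
  double ph_c = phi_conf(ic, p.c_e, p.i_th_c);

  d.ds_a = -s_a / p.tau_nmda + (1.0 - s_a) * p.gamma * r_a;
  d.ds_b = -s_b / p.tau_nmda + (1.0 - s_b) * p.gamma * r_b;
  d.ds_c = -s_c / p.tau_nmda + (1.0 - s_c) * p.gamma * r_c;
  d.dr_c = (p.rate_mode == 0) ? (ph_c - r_c) / p.tau_r
                              : -r_c / p.tau_r + ph_c;
  d.da = (p.variant == 0) ? (-a / p.tau_a + p.a_1 * r_c + p.a_0) : 0.0;
  if (p.variant == 1) {
    double r_pre = (p.std_site == 0) ? r_in : r_c;
    d.dx = (1.0 - x) / p.tau_d - p.u_0_eff * x * r_pre;
  } else {
    d.dx = 0.0;
  }
  d.r_a = r_a; d.r_b = r_b; d.i_a = ia; d.i_b = ib; d.i_c = ic;
  return d;
}

// [[Rcpp::export]]
List simulate_trial_cpp(List par, double t_start, double t_end,
                        double stim_onset, double stim_offset,
                        double coherence, int pref_b,
                        NumericMatrix noise_z, bool full_traces,
                        List init) {
  Pars p;
  p.tau_nmda = as<double>(par["tau_nmda"]);
  p.tau_a = as<double>(par["tau_a"]);
  p.tau_r = as<double>(par["tau_r"]);
  p.tau_d = as<double>(par["tau_d"]);
  p.gamma = as<double>(par["gamma"]);
  p.j_ii = as<double>(par["j_ii"]);
  p.j_ij = as<double>(par["j_ij"]);
  p.j_c = as<double>(par["j_c"]);
  p.j_fc = as<double>(par["j_fc"]);
  p.j_ext = as<double>(par["j_ext"]);
  p.j_dc = as<double>(par["j_dc"]);
  p.j_a_eff = as<double>(par["j_a"]) * as<double>(par["j_a_scale"]);
  p.c_e = as<double>(par["c_e"]);
  p.i_th = as<double>(par["i_th"]);
  p.g_e = as<double>(par["g_e"]);
  p.i_th_c = as<double>(par["i_th_c"]);
  p.a_1 = as<double>(par["a_1"]);
  p.a_0 = as<double>(par["a_0"]);
  p.mu_0 = as<double>(par["mu_0"]);
  p.u_0_eff = as<double>(par["u_0"]) * as<double>(par["u0_scale"]);
  p.i_0 = as<double>(par["i_0"]);
  p.i_0c = as<double>(par["i_0c"]);
  p.dt = as<double>(par["dt"]);
  p.noise_sigma = as<double>(par["noise_sigma"]);
  p.noise_tau = as<double>(par["noise_tau"]);
  std::string variant = as<std::string>(par["variant"]);
  p.variant = (variant == "adaptation") ? 0 : (variant == "std") ? 1 : 2;
  std::string mode = as<std::string>(par["rate_eq_mode"]);
  p.rate_mode = (mode == "relaxation") ? 0 : 1;
  std::string site = as<std::string>(par["std_site"]);
  p.std_site = (site == "feedforward") ? 0 : 1;

  const double dt = p.dt;
  const int n_steps = (int)std::lround((t_end - t_start) / dt);
  if (noise_z.nrow() != 3 || noise_z.ncol() < n_steps)
    stop("noise matrix must be 3 x n_steps");

  double base = p.j_ext * p.mu_0;
  double plus = base * (1.0 + coherence / 100.0);
  double minus = base * (1.0 - coherence / 100.0);
  double ext_a = pref_b ? minus : plus;
  double ext_b = pref_b ? plus : minus;

  double s_a = as<double>(init["s_a"]), s_b = as<double>(init["s_b"]),
         s_c = as<double>(init["s_c"]), r_c = as<double>(init["r_c"]),
         a = as<double>(init["a"]), x = as<double>(init["x"]),
         in_a = as<double>(init["i_noise_a"]),
         in_b = as<double>(init["i_noise_b"]),
         in_c = as<double>(init["i_noise_c"]);

  NumericVector tv(n_steps + 1), rA(n_steps + 1), rB(n_steps + 1),
      rC(n_steps + 1), iA(n_steps + 1), iB(n_steps + 1);
  NumericVector tr_sa, tr_sb, tr_sc, tr_a, tr_x, tr_na, tr_nb, tr_nc;
  if (full_traces) {
    tr_sa = NumericVector(n_steps + 1); tr_sb = NumericVector(n_steps + 1);
    tr_sc = NumericVector(n_steps + 1); tr_a = NumericVector(n_steps + 1);
    tr_x = NumericVector(n_steps + 1); tr_na = NumericVector(n_steps + 1);
    tr_nb = NumericVector(n_steps + 1); tr_nc = NumericVector(n_steps + 1);
  }

  const double decay = std::exp(-dt / p.noise_tau);
  const double diff_sd = p.noise_sigma * std::sqrt(1.0 - decay * decay);

  for (int k = 0; k <= n_steps; ++k) {
    double t = t_start + k * dt;
    // record the sample: rates are algebraic functions of the currents
    Deriv d0 = field(p, t, s_a, s_b, s_c, r_c, a, x, in_a, in_b, in_c,
                     stim_onset, stim_offset, ext_a, ext_b);
    tv[k] = t; rA[k] = d0.r_a; rB[k] = d0.r_b; rC[k] = r_c;
    iA[k] = d0.i_a; iB[k] = d0.i_b;
    if (full_traces) {
      tr_sa[k] = s_a; tr_sb[k] = s_b; tr_sc[k] = s_c; tr_a[k] = a;
      tr_x[k] = x; tr_na[k] = in_a; tr_nb[k] = in_b; tr_nc[k] = in_c;
    }
    if (!std::isfinite(s_a) || !std::isfinite(s_b) || !std::isfinite(r_c))
      stop("numerical failure at t = %f", t);
    if (k == n_steps) break;

    // midpoint RK2 on the deterministic part, noise frozen
    double m_sa = s_a + 0.5 * dt * d0.ds_a;
    double m_sb = s_b + 0.5 * dt * d0.ds_b;
    double m_sc = s_c + 0.5 * dt * d0.ds_c;
    double m_rc = r_c + 0.5 * dt * d0.dr_c;
    double m_a = a + 0.5 * dt * d0.da;
    double m_x = x + 0.5 * dt * d0.dx;
    Deriv d1 = field(p, t + 0.5 * dt, m_sa, m_sb, m_sc, m_rc, m_a, m_x,
                     in_a, in_b, in_c, stim_onset, stim_offset,
                     ext_a, ext_b);
    s_a += dt * d1.ds_a;
    s_b += dt * d1.ds_b;
    s_c += dt * d1.ds_c;
    r_c += dt * d1.dr_c;
    a += dt * d1.da;
    x += dt * d1.dx;

    // exact Ornstein--Uhlenbeck transition for the noise currents
    in_a = in_a * decay + diff_sd * noise_z(0, k);
    in_b = in_b * decay + diff_sd * noise_z(1, k);
    in_c = in_c * decay + diff_sd * noise_z(2, k);

    if (s_a < 0) s_a = 0; else if (s_a > 1) s_a = 1;
    if (s_b < 0) s_b = 0; else if (s_b > 1) s_b = 1;
    if (s_c < 0) s_c = 0; else if (s_c > 1) s_c = 1;
    if (x < 1e-12) x = 1e-12; else if (x > 1) x = 1;
    if (r_c < 0) r_c = 0;
  }

  List out = List::create(
      _["t"] = tv, _["r_a"] = rA, _["r_b"] = rB, _["r_c"] = rC,
      _["i_a"] = iA, _["i_b"] = iB);
  if (full_traces) {
    out["s_a"] = tr_sa; out["s_b"] = tr_sb; out["s_c"] = tr_sc;
    out["a"] = tr_a; out["x"] = tr_x;
    out["i_noise_a"] = tr_na; out["i_noise_b"] = tr_nb;
    out["i_noise_c"] = tr_nc;
  }
  return out;
}
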