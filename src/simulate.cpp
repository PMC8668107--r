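// Integration core for the early olfactory system model.
//
// Two stages: (1) sensilla -- transduction + ORN LIF with adaptation and
// ephaptic (NSI) coupling between the two co-housed ORNs; (2) antennal
// lobe -- conductance-based synapses, PN LIF with adaptation, LN LIF,
// cross-glomerular inhibition.  Gating/adaptation/synaptic variables use
// forward Euler; membrane potentials of PNs and LNs use an exact
// exponential decay step because their membrane time constant (C/gl =
// 0.1 ms) equals the integration step.  All randomness comes from R's RNG
// so results are reproducible via set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List run_sensilla_cpp(NumericVector conc_a, NumericVector conc_b, double dt,
                      List tr, List orn, int n_sensilla, double omega_nsi,
                      NumericMatrix sens) {
  const double n_hill = tr["n"], alpha_r = tr["alpha_r"],
               beta_r = tr["beta_r"], c0 = tr["c0"],
               r_noise = tr["r_noise"];
  const double C = orn["C"], gl = orn["gl"], V_rest = orn["V_rest"],
               V_rev = orn["V_rev"], V_K = orn["V_K"], g_r = orn["g_r"],
               g_y = orn["g_y"], alpha_y = orn["alpha_y"],
               beta_y = orn["beta_y"], theta = orn["theta"],
               tau_ref = orn["tau_ref"];
  const int n_t = conc_a.size();
  const int n_neu = 2 * n_sensilla;  // neuron index = 2*sensillum + type

  std::vector<double> r(n_neu), V(n_neu, V_rest), y(n_neu, 0.0),
                      refr(n_neu, 0.0), zeta(n_neu, 0.0);
  std::vector<std::vector<double> > spikes(n_neu);

  // initialize r at its steady state for the t=0 input
  for (int j = 0; j < n_neu; ++j) {
    int k = j % 2;
    double c = sens(k, 0) * conc_a[0] + sens(k, 1) * conc_b[0] + c0;
    double a = alpha_r * std::pow(c, n_hill);
    r[j] = a / (a + beta_r);
  }

  // white receptor noise: per-step sd referenced to the 0.1 ms calibration
  // step so that its integrated effect is dt-invariant
  const double noise_sd = r_noise * std::sqrt(0.1 / dt);

  for (int i = 0; i < n_t; ++i) {
    double t = i * dt;
    for (int s = 0; s < n_sensilla; ++s) {
      int ja = 2 * s, jb = 2 * s + 1;
      // receptor noise (Ornstein-Uhlenbeck) and transduction update
      double r_old_a = r[ja], r_old_b = r[jb];
      for (int k = 0; k < 2; ++k) {
        int j = (k == 0) ? ja : jb;
        double c = sens(k, 0) * conc_a[i] + sens(k, 1) * conc_b[i] + c0;
        if (r_noise > 0) zeta[j] = noise_sd * norm_rand();
        double drive = alpha_r * std::pow(c, n_hill);
        double rj = r[j] + dt * (drive * (1.0 - r[j]) - beta_r * r[j]);
        r[j] = rj < 0.0 ? 0.0 : (rj > 1.0 ? 1.0 : rj);
      }
      // membrane update; ephaptic coupling shifts the receptor-current
      // reversal by the partner's (pre-update) receptor activation
      for (int k = 0; k < 2; ++k) {
        int j = (k == 0) ? ja : jb;
        double r_partner = (k == 0) ? r_old_b : r_old_a;
        if (refr[j] > 0) {
          refr[j] -= dt;
          V[j] = V_rest;
        } else {
          double vrev_eff = V_rev - omega_nsi * r_partner * (V_rev - V_rest);
          double I = gl * (V_rest - V[j]) + g_y * y[j] * (V_K - V[j]) +
                     g_r * (r[j] + zeta[j]) * (vrev_eff - V[j]);
          V[j] += dt * I / C;
        }
        y[j] -= dt * beta_y * y[j];
        if (refr[j] <= 0 && V[j] > theta) {
          spikes[j].push_back(t);
          V[j] = V_rest;
          refr[j] = tau_ref;
          y[j] += alpha_y;
        }
      }
    }
  }

  List out(n_neu);
  for (int j = 0; j < n_neu; ++j) out[j] = wrap(spikes[j]);
  return out;
}

// advance an index over sorted spike times up to time t_hi, applying the
// saturating release jump once per spike
static inline void apply_spikes(const NumericVector& ts, int& idx,
                                double t_hi, double alpha, double& act) {
  while (idx < ts.size() && ts[idx] < t_hi) {
    act += alpha * (1.0 - act);
    ++idx;
  }
}

// [[Rcpp::export]]
List run_network_cpp(List orn_spikes, double t_total, double dt, List pn,
                     List ln, List syn, double C, double alpha_ln_eff,
                     int n_orn, int n_pn, int n_ln) {
  const double pn_gl = pn["gl"], pn_Vrest = pn["V_rest"],
               pn_theta = pn["theta"], pn_tref = pn["tau_ref"],
               VrevE = pn["V_revE"], VrevI = pn["V_revI"],
               g_orn = pn["g_orn"], g_ln = pn["g_ln"], g_ad = pn["g_ad"],
               alpha_ad = pn["alpha_ad"], tau_ad = pn["tau_ad"],
               pn_noise = pn["I_noise"];
  const double ln_gl = ln["gl"], ln_Vrest = ln["V_rest"],
               ln_theta = ln["theta"], ln_tref = ln["tau_ref"],
               ln_VrevE = ln["V_revE"], g_pn = ln["g_pn"],
               ln_noise = ln["I_noise"];
  const double a_orn = syn["alpha_orn"], tau_orn = syn["tau_orn"],
               a_pn = syn["alpha_pn"], tau_pn = syn["tau_pn"],
               tau_ln = syn["tau_ln"];

  const int n_t = (int)std::floor(t_total / dt) + 1;
  const int N_ORN = 2 * n_orn, N_PN = 2 * n_pn, N_LN = 2 * n_ln;

  std::vector<double> s_hat(N_ORN, 0.0), z_hat(N_PN, 0.0), y_hat(N_LN, 0.0);
  std::vector<int> orn_idx(N_ORN, 0);
  std::vector<double> Vp(N_PN, pn_Vrest), xp(N_PN, 0.0), refp(N_PN, 0.0);
  std::vector<double> Vl(N_LN, ln_Vrest), refl(N_LN, 0.0);
  std::vector<std::vector<double> > pn_sp(N_PN), ln_sp(N_LN);
  std::vector<NumericVector> orn_ts(N_ORN);
  for (int j = 0; j < N_ORN; ++j) orn_ts[j] = orn_spikes[j];

  const double pn_noise_dV = pn_noise * std::sqrt(dt) / C;
  const double ln_noise_dV = ln_noise * std::sqrt(dt) / C;

  for (int i = 0; i < n_t; ++i) {
    double t = i * dt;
    // synaptic decay
    for (int j = 0; j < N_ORN; ++j) s_hat[j] -= dt * s_hat[j] / tau_orn;
    for (int j = 0; j < N_PN; ++j) z_hat[j] -= dt * z_hat[j] / tau_pn;
    for (int j = 0; j < N_LN; ++j) y_hat[j] -= dt * y_hat[j] / tau_ln;
    // presynaptic ORN spikes up to current time
    for (int j = 0; j < N_ORN; ++j)
      apply_spikes(orn_ts[j], orn_idx[j], t, a_orn, s_hat[j]);
    // pooled activations per glomerulus (all-to-all within blocks)
    double S[2] = {0, 0}, Z[2] = {0, 0}, Y[2] = {0, 0};
    for (int j = 0; j < N_ORN; ++j) S[j / n_orn] += s_hat[j];
    for (int j = 0; j < N_PN; ++j) Z[j / n_pn] += z_hat[j];
    for (int j = 0; j < N_LN; ++j) Y[j / n_ln] += y_hat[j];

    // projection neurons: excitatory ORN drive, adaptation current and
    // cross-glomerular LN inhibition (both with inhibitory reversal)
    for (int j = 0; j < N_PN; ++j) {
      int g = j / n_pn;
      double y_in = Y[1 - g];
      if (refp[j] > 0) {
        refp[j] -= dt;
        Vp[j] = pn_Vrest;
      } else {
        double gtot = pn_gl + g_orn * S[g] + g_ad * xp[j] + g_ln * y_in;
        double vinf = (pn_gl * pn_Vrest + g_orn * S[g] * VrevE +
                       (g_ad * xp[j] + g_ln * y_in) * VrevI) / gtot;
        Vp[j] = vinf + (Vp[j] - vinf) * std::exp(-gtot * dt / C);
        Vp[j] += pn_noise_dV * norm_rand();
      }
      xp[j] -= dt * xp[j] / tau_ad;
      if (refp[j] <= 0 && Vp[j] > pn_theta) {
        pn_sp[j].push_back(t);
        Vp[j] = pn_Vrest;
        refp[j] = pn_tref;
        xp[j] += alpha_ad * (1.0 - xp[j]);
        z_hat[j] += a_pn * (1.0 - z_hat[j]);
      }
    }
    // local neurons: excitatory drive from PNs of the same glomerulus
    for (int j = 0; j < N_LN; ++j) {
      int g = j / n_ln;
      if (refl[j] > 0) {
        refl[j] -= dt;
        Vl[j] = ln_Vrest;
      } else {
        double gtot = ln_gl + g_pn * Z[g];
        double vinf = (ln_gl * ln_Vrest + g_pn * Z[g] * ln_VrevE) / gtot;
        Vl[j] = vinf + (Vl[j] - vinf) * std::exp(-gtot * dt / C);
        Vl[j] += ln_noise_dV * norm_rand();
      }
      if (refl[j] <= 0 && Vl[j] > ln_theta) {
        ln_sp[j].push_back(t);
        Vl[j] = ln_Vrest;
        refl[j] = ln_tref;
        y_hat[j] += alpha_ln_eff * (1.0 - y_hat[j]);
      }
    }
  }

  List pn_out(N_PN), ln_out(N_LN);
  for (int j = 0; j < N_PN; ++j) pn_out[j] = wrap(pn_sp[j]);
  for (int j = 0; j < N_LN; ++j) ln_out[j] = wrap(ln_sp[j]);
  return List::create(_["pn"] = pn_out, _["ln"] = ln_out);
}
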