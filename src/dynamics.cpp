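#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integrator for the excitatory/inhibitory competition.
//
// State columns: 0 E, 1 I, 2 A, 3 U, 4 S, 5 R, 6 X.  `cmat` holds the
// pairwise collision rates C[j][k].  Event impulses are applied by the
// caller between calls; this routine only evolves the continuous part:
// leaky decay of the rate estimators, the OU noise, adaptation, and the
// sigmoid-bounded E/I updates.
//
// par: 0 tau_ei, 1 tau_success, 2 tau_collision, 3 tau_noise, 4 tau_adapt,
//      5 tau_rate, 6 tau_rediscovery (all ms),
//      7 w_inh_to_exc, 8 w_exc_to_inh, 9 w_self_exc, 10 w_success,
//      11 w_collision, 12 w_noise, 13 w_adapt, 14 w_rediscovery,
//      15 denom_const, 16 theta_exc, 17 theta_inh, 18 sigma_noise
//
// Samples every `decim` global steps (global step counter starts at
// `step0`) are written to the trace matrices.

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
List dyn_integrate_cpp(NumericMatrix state, NumericMatrix cmat,
                       NumericVector par, int nsteps, double dt,
                       bool noise_on, bool adapt_on,
                       int decim, double step0) {
  const int k = state.nrow();
  NumericMatrix st = clone(state);
  NumericMatrix cm = clone(cmat);

  const double tau_ei = par[0], tau_s = par[1], tau_c = par[2],
    tau_n = par[3], tau_a = par[4], tau_r = par[5], tau_x = par[6];
  const double w_ie = par[7], w_ei = par[8], w_se = par[9], w_s = par[10],
    w_c = par[11], w_n = par[12], w_a = par[13], w_x = par[14],
    denom = par[15], th_e = par[16], th_i = par[17], sig_u = par[18];

  const double dS = std::exp(-dt / tau_s), dC = std::exp(-dt / tau_c),
    dR = std::exp(-dt / tau_r), dX = std::exp(-dt / tau_x);
  const double ou_g = dt / tau_n, ou_s = sig_u * std::sqrt(2.0 * dt / tau_n);

  const long long g0 = (long long)(step0 + 0.5);
  int nsamp = 0;
  for (int s = 1; s <= nsteps; s++)
    if ((g0 + s) % decim == 0) nsamp++;
  NumericMatrix tr(nsamp * 7, std::max(k, 1));
  IntegerVector samp_step(nsamp);

  std::vector<double> newE(k);
  int row = 0;
  for (int s = 1; s <= nsteps; s++) {
    for (int j = 0; j < k; j++) {
      double E = st(j, 0), I = st(j, 1), A = st(j, 2), U = st(j, 3),
        S = st(j, 4), R = st(j, 5), X = st(j, 6);
      double norm = R + denom;
      double coll = 0.0;
      for (int q = 0; q < k; q++)
        if (q != j) coll += cm(j, q) * st(q, 0);
      double inE = w_s * S / norm + w_x * X / norm + w_se * E * (1.0 - A)
        - w_ie * I - th_e;
      if (noise_on) inE += w_n * U;
      double inI = w_ei * E + w_c * coll / norm - th_i;
      newE[j] = E + dt / tau_ei * (-E + sigmoid(inE));
      st(j, 1) = I + dt / tau_ei * (-I + sigmoid(inI));
      if (adapt_on) st(j, 2) = A + dt / tau_a * (-A + w_a * E);
      if (noise_on) st(j, 3) = U - U * ou_g + ou_s * norm_rand();
      st(j, 4) = S * dS;
      st(j, 5) = R * dR;
      st(j, 6) = X * dX;
      for (int q = 0; q < k; q++) cm(j, q) *= dC;
    }
    for (int j = 0; j < k; j++) st(j, 0) = newE[j];
    if ((g0 + s) % decim == 0) {
      for (int j = 0; j < k; j++)
        for (int v = 0; v < 7; v++) tr(row * 7 + v, j) = st(j, v);
      samp_step[row] = (int)(step0 + s);
      row++;
    }
  }
  return List::create(_["state"] = st, _["cmat"] = cm,
                      _["traces"] = tr, _["samp_step"] = samp_step,
                      _["nsamp"] = nsamp);
}
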