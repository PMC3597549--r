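#' Competition-dynamics parameters
#'
#' Time constants and coupling weights of the excitatory/inhibitory
#' competition between chains.  Each competitive chain carries eight state
#' variables: excitation `E` and inhibition `I` (both kept in (0, 1) by the
#' logistic sigmoid), adaptation `A`, an Ornstein-Uhlenbeck noise signal
#' `U`, and leaky-integrated rates of prediction successes `S`, input
#' events `R`, rediscoveries `X` (all per second), plus the pairwise
#' collision rates `C`.
#'
#' The excitatory input of chain j is
#' `w_success*S/(R+c) + w_rediscovery*X/(R+c) + w_self_exc*E*(1-A)
#'  - w_inh_to_exc*I + w_noise*U - theta_exc`,
#' its inhibitory input is
#' `w_exc_to_inh*E + w_collision*sum_k(C_jk*E_k)/(R+c) - theta_inh`, and
#' both are passed through the logistic sigmoid before a leaky relaxation
#' with time constant `tau_ei`.  Adaptation relaxes towards
#' `w_adapt * E` with time constant `tau_adapt` and divisively weakens the
#' self-excitation term, which reads `w_self_exc * E * (1 - A)`.  The divisive `(R + c)`
#' factor normalises the event-driven drives across presentation rates.
#'
#' `theta_exc`, `theta_inh` are the activation thresholds of the two
#' populations and `sigma_noise` the stationary standard deviation of the
#' noise signal; together they set the operating point of the competition
#' (see the package vignette for how their defaults were fixed).
#'
#' @param tau_ei excitation/inhibition time constant, ms. Default 50.
#' @param tau_success,tau_collision success/collision rate time constants,
#'   ms. Defaults 1000.
#' @param tau_noise noise fluctuation time constant, ms. Default 500.
#' @param tau_adapt adaptation time constant, ms. Default 5000.
#' @param tau_rate input event rate time constant, ms. Default 5000.
#' @param tau_rediscovery rediscovery rate time constant, ms. Default 5000.
#' @param w_inh_to_exc,w_exc_to_inh inhibition-to-excitation and
#'   excitation-to-inhibition weights. Defaults 8.1 and 1.
#' @param w_self_exc self-excitation weight. Default 3.2.
#' @param w_success,w_collision success and collision weights. Defaults
#'   3.8 and 3.
#' @param w_noise noise weight. Default 3.4.
#' @param w_adapt adaptation strength: the saturation level of `A` at
#'   full excitation. Default 0.1.
#' @param w_rediscovery rediscovery weight. Default 7.
#' @param denom_const constant added to the divisive rate term to prevent
#'   division by zero. Default 0.1.
#' @param theta_exc,theta_inh sigmoid thresholds of the excitatory and
#'   inhibitory populations.
#' @param sigma_noise stationary standard deviation of the noise signal.
#' @param integration_step forward-Euler step, ms. Default 1.
#' @return A list of class `dynamics_params`.
#' @export
dynamics_params <- function(tau_ei = 50,
                            tau_success = 1000,
                            tau_collision = 1000,
                            tau_noise = 500,
                            tau_adapt = 5000,
                            tau_rate = 5000,
                            tau_rediscovery = 5000,
                            w_inh_to_exc = 8.1,
                            w_exc_to_inh = 1,
                            w_self_exc = 3.2,
                            w_success = 3.8,
                            w_collision = 3,
                            w_noise = 3.4,
                            w_adapt = 0.1,
                            w_rediscovery = 7,
                            denom_const = 0.1,
                            theta_exc = 0.8,
                            theta_inh = 2.5,
                            sigma_noise = 0.048,
                            integration_step = 1) {
  p <- as.list(environment())
  taus <- p[grep("^tau", names(p))]
  ws <- p[grep("^w_", names(p))]
  stopifnot(all(unlist(taus) > 0), all(unlist(ws) >= 0), denom_const > 0,
            integration_step > 0, integration_step <= tau_ei / 10)
  class(p) <- "dynamics_params"
  p
}

dyn_par_vector <- function(p) {
  c(p$tau_ei, p$tau_success, p$tau_collision, p$tau_noise, p$tau_adapt,
    p$tau_rate, p$tau_rediscovery,
    p$w_inh_to_exc, p$w_exc_to_inh, p$w_self_exc, p$w_success,
    p$w_collision, p$w_noise, p$w_adapt, p$w_rediscovery,
    p$denom_const, p$theta_exc, p$theta_inh, p$sigma_noise)
}

DYN_VARS <- c("E", "I", "A", "U", "S", "R", "X")

#' Dynamical state of competing chains
#'
#' All eight per-chain state variables are initialised to zero when a chain
#' enters the competition, so a freshly admitted chain has to charge up its
#' success and event-rate estimates before it can compete.
#'
#' @param n number of chains.
#' @return A list with a `state` matrix (`n` rows, columns
#'   `E, I, A, U, S, R, X`) and an `n x n` collision-rate matrix `cmat`.
#' @export
dyn_state <- function(n) {
  list(state = matrix(0, n, 7, dimnames = list(NULL, DYN_VARS)),
       cmat = matrix(0, n, n))
}

## Event impulses: each occurrence adds 1/tau (tau in seconds) so that the
## leaky integrators are running averages in events per second -- the
## time-average of the estimator equals the true event rate regardless of
## its time constant.

register_success <- function(dyn, i, params) {
  dyn$state[i, "S"] <- dyn$state[i, "S"] + 1000 / params$tau_success
  dyn
}

register_collision <- function(dyn, i, j, params) {
  inc <- 1000 / params$tau_collision
  dyn$cmat[i, j] <- dyn$cmat[i, j] + inc
  dyn$cmat[j, i] <- dyn$cmat[j, i] + inc
  dyn
}

register_input_event <- function(dyn, params) {
  dyn$state[, "R"] <- dyn$state[, "R"] + 1000 / params$tau_rate
  dyn
}

register_rediscovery <- function(dyn, i, params) {
  dyn$state[i, "X"] <- dyn$state[i, "X"] + 1000 / params$tau_rediscovery
  dyn
}

#' Single-variable dynamical updates
#'
#' Reference implementations of the elementary updates used by the
#' integrator: the Ornstein-Uhlenbeck noise step (mean-reverting to zero
#' with time constant `tau_noise`, Gaussian increments scaled with the
#' square root of the step, stationary standard deviation `sigma_noise`)
#' and the adaptation step (`A` relaxes towards `w_adapt` times the
#' current excitation with time constant `tau_adapt`).
#'
#' @param u,a,e current values of the noise, adaptation and excitation
#'   variables (vectorised).
#' @param dt_ms integration step in ms.
#' @param params a [dynamics_params()].
#' @return The updated variable.
#' @export
ou_step <- function(u, dt_ms, params = dynamics_params()) {
  stopifnot(dt_ms > 0)
  u - u * dt_ms / params$tau_noise +
    params$sigma_noise * sqrt(2 * dt_ms / params$tau_noise) *
      stats::rnorm(length(u))
}

#' @rdname ou_step
#' @export
adaptation_step <- function(a, e, dt_ms, params = dynamics_params()) {
  a + dt_ms / params$tau_adapt * (-a + params$w_adapt * e)
}

logistic <- function(x) 1 / (1 + exp(-x))

## Pure-R mirror of the compiled integrator, used as an independent
## cross-check in the tests.  Consumes the same Gaussian draws in the same
## order as the C++ path.
dyn_integrate_r <- function(dyn, params, nsteps, noise_on = TRUE,
                            adapt_on = TRUE) {
  st <- dyn$state; cm <- dyn$cmat
  k <- nrow(st); dt <- params$integration_step
  dS <- exp(-dt / params$tau_success); dC <- exp(-dt / params$tau_collision)
  dR <- exp(-dt / params$tau_rate); dX <- exp(-dt / params$tau_rediscovery)
  for (s in seq_len(nsteps)) {
    E <- st[, "E"]; norm <- st[, "R"] + params$denom_const
    coll <- as.vector(cm %*% E)
    inE <- params$w_success * st[, "S"] / norm +
      params$w_rediscovery * st[, "X"] / norm +
      params$w_self_exc * E * (1 - st[, "A"]) -
      params$w_inh_to_exc * st[, "I"] - params$theta_exc +
      if (noise_on) params$w_noise * st[, "U"] else 0
    inI <- params$w_exc_to_inh * E + params$w_collision * coll / norm -
      params$theta_inh
    st[, "I"] <- st[, "I"] + dt / params$tau_ei * (-st[, "I"] + logistic(inI))
    if (adapt_on)
      st[, "A"] <- st[, "A"] +
        dt / params$tau_adapt * (-st[, "A"] + params$w_adapt * E)
    if (noise_on)
      st[, "U"] <- st[, "U"] - st[, "U"] * dt / params$tau_noise +
        params$sigma_noise * sqrt(2 * dt / params$tau_noise) * stats::rnorm(k)
    st[, "S"] <- st[, "S"] * dS
    st[, "R"] <- st[, "R"] * dR
    st[, "X"] <- st[, "X"] * dX
    cm <- cm * dC
    st[, "E"] <- E + dt / params$tau_ei * (-E + logistic(inE))
  }
  list(state = st, cmat = cm)
}
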