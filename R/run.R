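## Two independent RNG substreams per run (assembly draws vs dynamics
## noise), so either stage's stochasticity can be toggled or replayed
## without disturbing the other.
rng_streams <- function(seed) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2)
  rs <- new.env(parent = emptyenv())
  set.seed(seeds[1]); rs$asm <- get(".Random.seed", globalenv())
  set.seed(seeds[2]); rs$dyn <- get(".Random.seed", globalenv())
  rs$active <- NA_character_
  rs
}

rng_use <- function(rs, name) {
  if (identical(rs$active, name)) return(invisible(NULL))
  if (!is.na(rs$active)) rs[[rs$active]] <- get(".Random.seed", globalenv())
  assign(".Random.seed", rs[[name]], envir = globalenv())
  rs$active <- name
  invisible(NULL)
}

## canonical closed chains for an ABA- train, used for pre-installed runs
canonical_chain <- function(which, delta_f, delta_t, base_frequency_hz = 400,
                            params = assembly_params()) {
  f_a <- base_frequency_hz
  f_b <- base_frequency_hz * 2^(delta_f / 12)
  spec <- switch(which,
    ABA = list(off = c(0, delta_t, 2 * delta_t), fr = c(f_a, f_b, f_a),
               per = 4 * delta_t, t0 = -4 * delta_t),
    A = list(off = 0, fr = f_a, per = 2 * delta_t, t0 = -2 * delta_t),
    B = list(off = 0, fr = f_b, per = 4 * delta_t, t0 = delta_t - 4 * delta_t),
    stop("unknown canonical chain: ", which))
  ch <- new_closed_chain(0L, spec$off, spec$fr, spec$per, spec$t0,
                         close_t = 0, close_n = 0L, params)
  ch$status <- "competitive"
  ch$admitted <- 0
  ch$pred_j <- 1L
  ch
}

#' Simulate one trial of the streaming model
#'
#' Runs the full two-stage model on a tone sequence: event-driven chain
#' discovery (open chains grow by probabilistic inclusion/skipping, close
#' into predictive loops, survive a probation cycle and enter the
#' competition with probability `p_compete`), and the continuous
#' excitatory/inhibitory competition between the admitted chains, read out
#' into a time series of integrated/segregated percept labels and a table
#' of perceptual phases.
#'
#' @param delta_f frequency separation in semitones (ignored when `events`
#'   is given).
#' @param delta_t onset-to-onset interval in ms (ignored when `events` is
#'   given).
#' @param duration_s trial duration in seconds. Default 240.
#' @param seed integer seed; one run is fully reproducible from it.
#' @param events optional [event_sequence()] replacing the ABA- train.
#' @param base_frequency_hz A-tone frequency for the ABA- train.
#' @param assembly an [assembly_params()].
#' @param dynamics a [dynamics_params()].
#' @param noise,adaptation,rediscovery ablation switches; setting one to
#'   `FALSE` removes the corresponding term from the dynamics.
#' @param discover run the pattern-discovery stage (default). With
#'   `discover = FALSE` only pre-installed chains compete.
#' @param preinstall chains installed as competitive at t = 0: a character
#'   subset of `c("ABA", "A", "B")` (canonical chains for the ABA- train)
#'   or a list of closed-chain records.
#' @param init_state optional numeric matrix (chains x 7, columns
#'   `E,I,A,U,S,R,X`) of initial dynamical states for pre-installed chains;
#'   default all zero.
#' @param init_collisions optional square matrix of initial pairwise
#'   collision rates for pre-installed chains.
#' @param trace_every_ms decimation of the stored state traces. Default 10.
#' @param filter_tau_ms readout low-pass time constant. Default 500.
#' @param min_phase_ms phases shorter than this are absorbed (set 0 to
#'   keep all). Default 300.
#' @param keep_traces store the per-chain state traces in the result.
#' @return An object of class `chains_run`: a list with the phase table
#'   (`phases`), the label time series (`labels`, `label_times_ms`), the
#'   chain log (`chains`), the traces, and the call conditions.
#' @examples
#' \donttest{
#' r <- chains_run(16, 200, duration_s = 60, seed = 1)
#' r
#' }
#' @export
chains_run <- function(delta_f = 16, delta_t = 200, duration_s = 240,
                       seed = 1, events = NULL, base_frequency_hz = 400,
                       assembly = assembly_params(),
                       dynamics = dynamics_params(),
                       noise = TRUE, adaptation = TRUE, rediscovery = TRUE,
                       discover = TRUE, preinstall = NULL, init_state = NULL,
                       init_collisions = NULL,
                       trace_every_ms = 10, filter_tau_ms = 500,
                       min_phase_ms = 300, keep_traces = TRUE) {
  custom_events <- !is.null(events)
  if (is.null(events)) {
    events <- aba_train(delta_f, delta_t, duration_s, base_frequency_hz)
    span_fallback <- 8 * delta_t
  } else {
    stopifnot(inherits(events, "event_sequence"))
    duration_s <- attr(events, "total_duration_ms") / 1000
    gaps <- diff(events$onset_ms)
    span_fallback <- if (length(gaps)) 8 * min(gaps) else 2000
  }
  dur_ms <- duration_s * 1000
  dt <- dynamics$integration_step
  decim <- trace_every_ms / dt
  stopifnot(abs(decim - round(decim)) < 1e-9)
  decim <- as.integer(round(decim))

  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  }, add = TRUE)
  rs <- rng_streams(seed)

  ast <- asm_new_state(assembly, span_fallback)
  if (!is.null(preinstall)) {
    if (is.character(preinstall))
      preinstall <- lapply(preinstall, canonical_chain, delta_f = delta_f,
                           delta_t = delta_t,
                           base_frequency_hz = base_frequency_hz,
                           params = assembly)
    for (i in seq_along(preinstall)) {
      ch <- preinstall[[i]]
      ch$id <- ast$next_id; ast$next_id <- ast$next_id + 1L
      ast$closed[[length(ast$closed) + 1L]] <- ch
    }
  }

  n_samp <- floor(dur_ms / trace_every_ms)
  meta <- data.frame(id = integer(0), col = integer(0), both_class = logical(0),
                     admitted = numeric(0), died = numeric(0))
  tr <- lapply(DYN_VARS, function(v) matrix(NA_real_, n_samp, 0))
  names(tr) <- DYN_VARS
  dyn <- dyn_state(0)
  par_vec <- dyn_par_vector(dynamics)

  ## add/remove chains from the dynamical arrays
  add_chain <- function(ch, state0 = NULL) {
    k <- nrow(dyn$state)
    st <- rbind(dyn$state, if (is.null(state0)) rep(0, 7) else state0)
    cm <- matrix(0, k + 1, k + 1)
    if (k) cm[1:k, 1:k] <- dyn$cmat
    dyn <<- list(state = st, cmat = cm)
    for (v in DYN_VARS) tr[[v]] <<- cbind(tr[[v]], NA_real_)
    meta <<- rbind(meta, data.frame(id = ch$id, col = k + 1L,
                                    both_class = ch$both_class,
                                    admitted = ch$admitted, died = NA_real_))
  }
  drop_chain <- function(id, t) {
    i <- match(id, meta$id)
    meta$died[i] <<- t
    col <- meta$col[i]
    live <- which(is.na(meta$died))
    keep <- meta$col[live]
    dyn <<- list(state = dyn$state[keep, , drop = FALSE],
                 cmat = dyn$cmat[keep, keep, drop = FALSE])
    meta$col[live] <<- seq_along(live)
    meta$col[i] <<- NA_integer_
  }
  if (!is.null(preinstall)) {
    for (i in seq_along(ast$closed)) {
      ch <- ast$closed[[i]]
      st0 <- if (!is.null(init_state)) init_state[i, ] else NULL
      add_chain(ch, st0)
    }
    if (!is.null(init_collisions))
      dyn$cmat[] <- init_collisions
  }

  integrate_to <- function(t_target) {
    nsteps <- as.integer(round((t_target - t_cur) / dt))
    if (nsteps <= 0) return(invisible(NULL))
    k <- nrow(dyn$state)
    if (k > 0) {
      rng_use(rs, "dyn")
      res <- dyn_integrate_cpp(dyn$state, dyn$cmat, par_vec, nsteps, dt,
                               noise, adaptation, decim, step0)
      dyn <<- list(state = res$state, cmat = res$cmat)
      if (res$nsamp > 0) {
        rows <- res$samp_step %/% decim
        ok <- rows >= 1 & rows <= n_samp
        live <- which(is.na(meta$died))
        for (v in seq_along(DYN_VARS)) {
          vals <- res$traces[seq(v, res$nsamp * 7, by = 7), , drop = FALSE]
          tr[[v]][rows[ok], live] <<- vals[ok, meta$col[live], drop = FALSE]
        }
      }
    }
    step0 <<- step0 + nsteps
    t_cur <<- t_target
    invisible(NULL)
  }

  t_cur <- 0; step0 <- 0
  ## global input-event-rate estimator: every chain's R tracks the same
  ## input, so a chain admitted mid-run starts from the current estimate
  ## rather than zero (its private S still charges from zero, giving the
  ## admission inertia).
  r_global <- 0; r_global_t <- 0
  s_inc <- 1000 / dynamics$tau_success
  c_inc <- 1000 / dynamics$tau_collision
  r_inc <- 1000 / dynamics$tau_rate
  x_inc <- 1000 / dynamics$tau_rediscovery
  ast$discover <- discover

  for (ei in seq_len(nrow(events))) {
    t_e <- events$onset_ms[ei]; f_e <- events$frequency_hz[ei]
    integrate_to(t_e)
    r_global <- r_global * exp(-(t_e - r_global_t) / dynamics$tau_rate) + r_inc
    r_global_t <- t_e
    rng_use(rs, "asm")
    res <- asm_process_event(ast, t_e, f_e, discover = discover)
    for (id in res$removals) drop_chain(id, t_e)
    k <- nrow(dyn$state)
    if (k > 0) {
      live <- which(is.na(meta$died))
      dyn$state[, "R"] <- dyn$state[, "R"] + r_inc
      pr <- match(res$predictors, meta$id[live])
      pr <- stats::na.omit(pr)
      if (length(pr)) {
        cols <- meta$col[live][pr]
        dyn$state[cols, "S"] <- dyn$state[cols, "S"] + s_inc
        if (length(cols) > 1) {
          for (a in seq_along(cols)[-length(cols)])
            for (b in (a + 1):length(cols)) {
              dyn$cmat[cols[a], cols[b]] <- dyn$cmat[cols[a], cols[b]] + c_inc
              dyn$cmat[cols[b], cols[a]] <- dyn$cmat[cols[b], cols[a]] + c_inc
            }
        }
      }
      if (rediscovery && length(res$rediscoveries)) {
        rd <- match(res$rediscoveries, meta$id[live])
        rd <- stats::na.omit(rd)
        if (length(rd)) {
          cols <- meta$col[live][rd]
          dyn$state[cols, "X"] <- dyn$state[cols, "X"] + x_inc
        }
      }
    }
    for (ch in res$admissions) {
      st0 <- rep(0, 7)
      st0[6] <- r_global
      add_chain(ch, st0)
    }
  }
  integrate_to(dur_ms)
  rng_use(rs, "asm")
  removals <- asm_finalize(ast, dur_ms)
  for (id in removals) drop_chain(id, dur_ms)

  ## readout
  if (ncol(tr$E)) {
    e_filt <- lowpass(tr$E, trace_every_ms, filter_tau_ms)
    if (is.null(dim(e_filt))) e_filt <- matrix(e_filt, ncol = ncol(tr$E))
    labels <- classify_percept(e_filt, meta$both_class)
  } else {
    e_filt <- tr$E
    labels <- integer(n_samp)
  }
  phases <- extract_phases(labels, trace_every_ms, min_phase_ms)

  structure(list(
    condition = list(delta_f = delta_f, delta_t = delta_t,
                     duration_s = duration_s,
                     base_frequency_hz = base_frequency_hz,
                     custom_events = custom_events),
    seed = seed,
    params = list(assembly = assembly, dynamics = dynamics),
    ablations = list(noise = !noise, adaptation = !adaptation,
                     rediscovery = !rediscovery),
    events = events,
    chains = chain_log_df(ast),
    labels = labels,
    label_times_ms = seq_len(n_samp) * trace_every_ms,
    phases = phases,
    meta = meta,
    traces = if (keep_traces) c(tr, list(E_filt = e_filt)) else NULL
  ), class = "chains_run")
}

## flatten the assembly log (plus still-alive chains) into a data frame
chain_log_df <- function(ast) {
  recs <- ast$log
  if (!length(recs))
    return(data.frame(id = integer(0), period = numeric(0),
                      n_events = integer(0), both_class = logical(0),
                      freq_lo = numeric(0), freq_hi = numeric(0),
                      closed_ms = numeric(0), admitted_ms = numeric(0),
                      died_ms = numeric(0), status = character(0),
                      rediscoveries = integer(0)))
  df <- do.call(rbind, lapply(recs, function(ch) data.frame(
    id = ch$id, period = ch$period, n_events = length(ch$offsets),
    both_class = ch$both_class, freq_lo = min(ch$freqs),
    freq_hi = max(ch$freqs), closed_ms = ch$close_t,
    admitted_ms = ch$admitted, died_ms = ch$died,
    status = ch$status, rediscoveries = ch$redisc)))
  df <- df[order(df$id), ]
  rownames(df) <- NULL
  df
}
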