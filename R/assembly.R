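#' Chain-building parameters
#'
#' Parameters of the pattern-discovery stage: the link-formation
#' coefficients, the matching widths that define when two events (or an
#' event and a prediction) count as "the same", the probability that a
#' newly verified chain enters the competition, and the caps that keep the
#' open-chain population finite.
#'
#' Abrupt transitions are expensive to include and easy to skip: the
#' inclusion cost grows with the squared feature jump `d^2` (d in
#' semitones) and links across long gaps are discounted by
#' `exp(-dt/tau_link)`; the skipping probability grows with the rate of
#' change `d^2/dt` (semitones squared per second).
#'
#' @param beta_include_rate weight of the rate-of-change cost in the
#'   inclusion probability. Default 0.00015.
#' @param beta_include_npred weight of the number of competing chains that
#'   already predict the incoming event (explaining away). Default 1.
#' @param beta_skip_rate weight of the rate-of-change cost in the skipping
#'   probability. Default 0.0055.
#' @param beta_skip_ndiff weight of the difference in how often the two
#'   events are predicted, in the skipping probability. Default 8.
#' @param match_width_time half-width of the temporal matching window, ms.
#'   Default 30.
#' @param match_width_feature half-width of the feature matching window,
#'   semitones. Default 0.5.
#' @param p_compete probability that a chain which survives its probation
#'   cycle enters the competition. Default 0.2.
#' @param max_open_length maximum number of nodes in an open chain before
#'   it is deleted. Default 6.
#' @param tau_link temporal-proximity scale of link formation, ms: the
#'   inclusion probability carries a factor `exp(-dt/tau_link)`, so links
#'   across long gaps are hard to form and temporal proximity favours
#'   patterns built from adjacent tones. Default 500.
#' @param max_open_span maximum age (ms, from its first event) an open
#'   chain may reach without closing.  `NULL` means "choose from the
#'   stimulus": the simulation runners use twice the longest expected
#'   pattern period, i.e. `8 * delta_t` for ABA- trains; for arbitrary
#'   sequences the fallback is 2000 ms.
#' @return A list of class `assembly_params`.
#' @export
assembly_params <- function(beta_include_rate = 0.00015,
                            beta_include_npred = 1,
                            beta_skip_rate = 0.0055,
                            beta_skip_ndiff = 8,
                            match_width_time = 30,
                            match_width_feature = 0.5,
                            p_compete = 0.2,
                            tau_link = 500,
                            max_open_length = 6,
                            max_open_span = NULL) {
  p <- list(beta_include_rate = beta_include_rate,
            beta_include_npred = beta_include_npred,
            beta_skip_rate = beta_skip_rate,
            beta_skip_ndiff = beta_skip_ndiff,
            match_width_time = match_width_time,
            match_width_feature = match_width_feature,
            p_compete = p_compete,
            tau_link = tau_link,
            max_open_length = max_open_length,
            max_open_span = max_open_span)
  stopifnot(all(vapply(p[1:4], function(x) is.finite(x) && x >= 0, TRUE)),
            match_width_time > 0, match_width_feature > 0, tau_link > 0,
            p_compete >= 0, p_compete <= 1, max_open_length >= 2)
  class(p) <- "assembly_params"
  p
}

## Inclusion: the cost of absorbing the next event is the squared feature
## jump (similarity), discounted by how many competing chains already
## predict the event, and by a temporal-proximity factor exp(-dt/tau_link)
## that makes links across long gaps hard to form.
.p_inc <- function(d_st, dt_ms, n_pred, par) {
  exp(-par$beta_include_rate * d_st * d_st -
        par$beta_include_npred * n_pred -
        dt_ms / par$tau_link)
}

## Skipping: driven by the rate of feature change (squared semitone jump
## per second of gap) and by the prediction imbalance dn, the excess
## prediction count of the skipped event over the chain's last event; only
## a positive excess (the skipped event is claimed by more chains)
## facilitates skipping.
.p_skip <- function(d_st, dt_ms, dn, par, blocked = FALSE) {
  ifelse(blocked, 0,
         1 - exp(-par$beta_skip_rate * d_st * d_st / (dt_ms / 1000) -
                   par$beta_skip_ndiff * pmax(0, dn)))
}

event_tf <- function(e) {
  if (is.numeric(e) && length(e) == 2) return(list(t = e[[1]], f = e[[2]]))
  list(t = e$onset_ms[[1]], f = e$frequency_hz[[1]])
}

#' Link-formation probabilities
#'
#' `p_include()` is the probability that an open chain ending in event
#' `prev` absorbs the incoming event `nxt`; it decays exponentially with
#' the squared feature jump (semitones), with the temporal gap (the
#' `tau_link` proximity factor), and with the number of competing chains
#' that already predict `nxt` (explaining away).  `p_skip()` is the
#' probability that the chain instead survives while leaving `nxt` out; it
#' grows with the rate of feature change `d^2/dt` and with the prediction
#' imbalance between the two events, and is exactly zero when `nxt`
#' matches, in feature, an event the chain has already incorporated (a
#' chain cannot skip an event it contains).
#'
#' @param prev,nxt events: either a one-row data frame with `onset_ms` and
#'   `frequency_hz` columns, or a numeric `c(time_ms, frequency_hz)` pair.
#'   `nxt` must be later than `prev`.
#' @param n_pred number of competing chains predicting `nxt`.
#' @param delta_n excess of the prediction count of `nxt` over that of
#'   `prev`; only a positive excess (the candidate for skipping is claimed
#'   by more chains than the chain's own last event) makes skipping
#'   easier.
#' @param included_freqs frequencies (Hz) of the events already
#'   incorporated in the chain; if `nxt` matches one of them within the
#'   feature matching width, the skip probability is 0.
#' @param params an [assembly_params()].
#' @return A probability in `[0, 1]`.
#' @examples
#' p_include(c(0, 400), c(200, 400 * 2^(16/12)))   # A -> B at the neutral condition
#' p_skip(c(0, 400), c(200, 400 * 2^(16/12)))
#' @export
p_include <- function(prev, nxt, n_pred = 0, params = assembly_params()) {
  a <- event_tf(prev); b <- event_tf(nxt)
  if (b$t <= a$t) stop("nxt must be strictly later than prev")
  .p_inc(semitone_distance(a$f, b$f), b$t - a$t, n_pred, params)
}

#' @rdname p_include
#' @export
p_skip <- function(prev, nxt, delta_n = 0, included_freqs = NULL,
                   params = assembly_params()) {
  a <- event_tf(prev); b <- event_tf(nxt)
  if (b$t <= a$t) stop("nxt must be strictly later than prev")
  blocked <- length(included_freqs) > 0 &&
    any(semitone_distance(included_freqs, b$f) < params$match_width_feature)
  .p_skip(semitone_distance(a$f, b$f), b$t - a$t, delta_n, params, blocked)
}

#' Event and prediction matching
#'
#' Two time/frequency points match when the normalised squared time
#' difference plus the normalised squared feature difference falls strictly
#' inside the ellipse whose half-axes are the temporal and feature matching
#' widths.  `match_time()` and `match_feature()` apply only the respective
#' one-dimensional criterion.
#'
#' @param e1,e2 events or predictions: one-row data frames with `onset_ms`
#'   and `frequency_hz`, or numeric `c(time_ms, frequency_hz)` pairs.
#' @param params an [assembly_params()].
#' @return logical.
#' @export
events_match <- function(e1, e2, params = assembly_params()) {
  a <- event_tf(e1); b <- event_tf(e2)
  .match_tf(a$t, a$f, b$t, b$f, params)
}

.match_tf <- function(t1, f1, t2, f2, par) {
  (((t1 - t2) / par$match_width_time)^2 +
     (semitone_distance(f1, f2) / par$match_width_feature)^2) < 1
}

#' @rdname events_match
#' @export
match_time <- function(e1, e2, params = assembly_params()) {
  abs(event_tf(e1)$t - event_tf(e2)$t) < params$match_width_time
}

#' @rdname events_match
#' @export
match_feature <- function(e1, e2, params = assembly_params()) {
  semitone_distance(event_tf(e1)$f, event_tf(e2)$f) < params$match_width_feature
}

## ------------------------------------------------------------------
## closed chains

new_closed_chain <- function(id, offsets, freqs, period, t0, close_t,
                             close_n, par) {
  list(id = id,
       offsets = offsets,         # intra-cycle onsets, offsets[1] == 0
       freqs = freqs,
       period = period,
       t0 = t0,                   # occurrence time of the cycle origin
       close_t = close_t,
       status = "probation",
       pred_j = 2L,               # global prediction index (1 = closing event)
       last_match_t = close_t,
       last_match_f = freqs[1],
       last_match_n = close_n,
       both_class = any(outer(freqs, freqs, function(a, b)
         semitone_distance(a, b)) >= par$match_width_feature),
       admitted = NA_real_, died = NA_real_, redisc = 0L)
}

pred_time <- function(ch, j) {
  k <- length(ch$offsets)
  ch$t0 + ((j - 1) %/% k + 1) * ch$period + ch$offsets[(j - 1) %% k + 1]
}

pred_freq <- function(ch, j) ch$freqs[(j - 1) %% length(ch$offsets) + 1]

## predictions of a closed chain in the half-open window (from, to]
chain_predictions <- function(ch, from, to) {
  k <- length(ch$offsets)
  m <- seq(floor((from - ch$t0) / ch$period) - 1,
           ceiling((to - ch$t0) / ch$period) + 1)
  t <- rep(m * ch$period, each = k) + ch$offsets + ch$t0
  f <- rep_len(ch$freqs, length(t))
  keep <- t > from & t <= to
  list(t = t[keep], f = f[keep])
}

#' Are two closed chains the same pattern?
#'
#' Two closed chains are equivalent when, over a horizon of two cycles of
#' the longer chain starting now, every prediction of one matches a
#' prediction of the other (inside the matching ellipse), and vice versa.
#' Used to detect rediscovery: a duplicate never enters the competition a
#' second time, it increments the original's rediscovery rate instead.
#'
#' @param c1,c2 closed-chain records (as found in a run's chain log).
#' @param now time (ms) from which the two prediction streams are compared;
#'   defaults to the later of the two closure times.
#' @param params an [assembly_params()].
#' @return logical.
#' @export
chains_equivalent <- function(c1, c2, now = NULL, params = assembly_params()) {
  if (is.null(now)) now <- max(c1$close_t, c2$close_t)
  horizon <- 2 * max(c1$period, c2$period)
  p1 <- chain_predictions(c1, now, now + horizon)
  p2 <- chain_predictions(c2, now, now + horizon)
  if (length(p1$t) == 0 || length(p2$t) == 0)
    return(length(p1$t) == length(p2$t))
  ok12 <- vapply(seq_along(p1$t), function(i)
    any(.match_tf(p1$t[i], p1$f[i], p2$t, p2$f, params)), TRUE)
  ok21 <- vapply(seq_along(p2$t), function(i)
    any(.match_tf(p2$t[i], p2$f[i], p1$t, p1$f, params)), TRUE)
  all(ok12) && all(ok21)
}

## ------------------------------------------------------------------
## assembly engine
##
## The open-chain population is held as a struct-of-arrays for vectorised
## branching; per-chain node lists are only touched on inclusion/closure.

asm_new_state <- function(params, span_fallback = 2000) {
  if (is.null(params$max_open_span)) params$max_open_span <- span_fallback
  env <- new.env(parent = emptyenv())
  env$par <- params
  env$open <- list(first_t = numeric(0), first_f = numeric(0),
                   last_t = numeric(0), last_f = numeric(0),
                   last_n = integer(0), nn = integer(0),
                   nt = list(), nf = list())
  env$closed <- list()        # probation + competitive chains, by position
  env$next_id <- 1L
  env$log <- list()           # terminal records of every closed chain
  env$last_event <- NULL
  env
}

## record a finished (or final-state) closed chain in the log
asm_log_chain <- function(st, ch) {
  st$log[[length(st$log) + 1L]] <- ch
  invisible(NULL)
}

## process one input event; returns the dynamical bookkeeping for the
## caller: which competitive chains predicted the event (successes and
## collisions), removals, admissions, rediscoveries, and n_pred(e).
asm_process_event <- function(st, t, f, force_include = FALSE,
                              force_skip = FALSE, force_admit = FALSE,
                              discover = TRUE) {
  par <- st$par
  wt <- par$match_width_time
  successes <- integer(0); removals <- integer(0)
  admissions <- list(); redisc <- integer(0)

  ## --- closed chains: expire, match, probe ------------------------
  keep <- rep(TRUE, length(st$closed))
  predictors <- integer(0)              # ids of competitive predictors
  for (i in seq_along(st$closed)) {
    ch <- st$closed[[i]]
    ## expire predictions no event can match any more -> failure
    if (pred_time(ch, ch$pred_j) < t - wt) {
      ch$died <- t
      asm_log_chain(st, ch)
      if (ch$status == "competitive") removals <- c(removals, ch$id)
      keep[i] <- FALSE
      next
    }
    pt <- pred_time(ch, ch$pred_j)
    if (.match_tf(pt, pred_freq(ch, ch$pred_j), t, f, par)) {
      ch$pred_j <- ch$pred_j + 1L
      ch$last_match_t <- t; ch$last_match_f <- f
      if (ch$status == "competitive") predictors <- c(predictors, ch$id)
      st$closed[[i]] <- ch
    }
  }
  st$closed <- st$closed[keep]

  ## how many competing chains predicted this event
  n_now <- length(predictors)

  if (!discover) {
    st$last_event <- c(t, f)
    return(list(predictors = predictors, n_pred = n_now,
                removals = removals, admissions = list(),
                rediscoveries = integer(0)))
  }

  ## --- probation: unpredicted events must be skipped; completed
  ##     cycles face the admission draw --------------------------------
  keep <- rep(TRUE, length(st$closed))
  for (i in seq_along(st$closed)) {
    ch <- st$closed[[i]]
    if (ch$status != "probation") { st$closed[[i]]$last_match_n <- if (ch$id %in% predictors) n_now else st$closed[[i]]$last_match_n; next }
    k <- length(ch$offsets)
    matched_now <- ch$last_match_t == t
    if (!matched_now) {
      ## event not predicted by this chain: must be skippable
      blocked <- any(semitone_distance(ch$freqs, f) < par$match_width_feature)
      ps <- .p_skip(semitone_distance(ch$last_match_f, f),
                    max(t - ch$last_match_t, 1e-9),
                    n_now - ch$last_match_n, par, blocked)
      ok <- if (force_skip) ps > 0 else stats::runif(1) < ps
      if (!ok) {
        ch$died <- t; asm_log_chain(st, ch); keep[i] <- FALSE
        next
      }
    } else {
      ch$last_match_n <- n_now
      if (ch$pred_j > k + 1L) {
        ## one clean cycle of predictions completed.  A duplicate of a
        ## chain already in the competition counts as a rediscovery and is
        ## discarded; only a novel chain faces the admission draw, since
        ## p_compete gates a chain *first* entering the competition.
        dup <- NA_integer_
        for (j in seq_along(st$closed)) {
          cj <- st$closed[[j]]
          if (cj$status == "competitive" &&
              chains_equivalent(cj, ch, now = t, params = par)) { dup <- cj$id; break }
        }
        if (!is.na(dup)) {
          redisc <- c(redisc, dup)
          dj <- which(vapply(st$closed, function(x) x$id, 0L) == dup)
          st$closed[[dj]]$redisc <- st$closed[[dj]]$redisc + 1L
          ch$died <- t; ch$status <- "duplicate"
          asm_log_chain(st, ch); keep[i] <- FALSE
        } else {
          ok <- if (force_admit) par$p_compete > 0 else stats::runif(1) < par$p_compete
          if (!ok) {
            ch$died <- t; asm_log_chain(st, ch); keep[i] <- FALSE
            next
          }
          ch$status <- "competitive"; ch$admitted <- t
          admissions[[length(admissions) + 1L]] <- ch
        }
      }
    }
    if (keep[i]) st$closed[[i]] <- ch
  }
  st$closed <- st$closed[keep]

  ## --- open chains: age cull, then include/skip branching ---------
  op <- st$open
  n_open <- length(op$first_t)
  if (n_open) {
    alive <- (t - op$first_t) <= par$max_open_span
    op <- lapply_open(op, alive)
    n_open <- length(op$first_t)
  }
  new_closed <- list()
  if (n_open) {
    d <- semitone_distance(op$last_f, f)
    dt <- t - op$last_t
    pi_ <- .p_inc(d, dt, n_now, par)
    blocked <- vapply(op$nf, function(v)
      any(semitone_distance(v, f) < par$match_width_feature), TRUE)
    ps_ <- .p_skip(d, dt, n_now - op$last_n, par, blocked)
    inc <- if (force_include) pi_ > 0 else stats::runif(n_open) < pi_
    skp <- if (force_skip) ps_ > 0 else stats::runif(n_open) < ps_
    ## inclusion: extended copies (respecting the length cap)
    ext_idx <- which(inc & (op$nn + 1L) <= par$max_open_length)
    surv <- lapply_open(op, skp)
    if (length(ext_idx)) {
      ext <- lapply_open(op, ext_idx)
      ext$nt <- lapply(ext$nt, function(v) c(v, t))
      ext$nf <- lapply(ext$nf, function(v) c(v, f))
      ext$last_t <- rep(t, length(ext_idx))
      ext$last_f <- rep(f, length(ext_idx))
      ext$last_n <- rep(n_now, length(ext_idx))
      ext$nn <- ext$nn + 1L
      ## closure: first and last events match in feature
      closes <- which(semitone_distance(ext$first_f, f) < par$match_width_feature)
      for (i in closes) {
        nt <- ext$nt[[i]]; nf <- ext$nf[[i]]
        k <- length(nt)
        ch <- new_closed_chain(st$next_id, nt[-k] - nt[1], nf[-k],
                               period = nt[k] - nt[1], t0 = nt[1],
                               close_t = t, close_n = n_now, par)
        st$next_id <- st$next_id + 1L
        new_closed[[length(new_closed) + 1L]] <- ch
      }
      surv <- bind_open(surv, ext)
    }
    op <- surv
  }
  ## every event starts a new singleton chain
  op$first_t <- c(op$first_t, t); op$first_f <- c(op$first_f, f)
  op$last_t <- c(op$last_t, t); op$last_f <- c(op$last_f, f)
  op$last_n <- c(op$last_n, n_now); op$nn <- c(op$nn, 1L)
  op$nt <- c(op$nt, list(t)); op$nf <- c(op$nf, list(f))
  st$open <- op
  st$closed <- c(st$closed, new_closed)
  st$last_event <- c(t, f)

  list(predictors = predictors, n_pred = n_now,
       removals = removals, admissions = admissions,
       rediscoveries = redisc)
}

## finish a run: expire predictions falling before t_end - width
asm_finalize <- function(st, t_end) {
  removals <- integer(0)
  keep <- rep(TRUE, length(st$closed))
  for (i in seq_along(st$closed)) {
    ch <- st$closed[[i]]
    if (pred_time(ch, ch$pred_j) < t_end - st$par$match_width_time) {
      ch$died <- t_end
      asm_log_chain(st, ch)
      if (ch$status == "competitive") removals <- c(removals, ch$id)
      keep[i] <- FALSE
    }
  }
  st$closed <- st$closed[keep]
  for (ch in st$closed) asm_log_chain(st, ch)
  removals
}

lapply_open <- function(op, idx) {
  list(first_t = op$first_t[idx], first_f = op$first_f[idx],
       last_t = op$last_t[idx], last_f = op$last_f[idx],
       last_n = op$last_n[idx], nn = op$nn[idx],
       nt = op$nt[idx], nf = op$nf[idx])
}

bind_open <- function(a, b) {
  list(first_t = c(a$first_t, b$first_t), first_f = c(a$first_f, b$first_f),
       last_t = c(a$last_t, b$last_t), last_f = c(a$last_f, b$last_f),
       last_n = c(a$last_n, b$last_n), nn = c(a$nn, b$nn),
       nt = c(a$nt, b$nt), nf = c(a$nf, b$nf))
}
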