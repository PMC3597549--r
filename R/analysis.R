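## helpers: pull phase tables / labels out of whatever "runs" we are given
phase_tables <- function(runs) {
  if (inherits(runs, "chains_condition")) runs <- runs$runs
  if (inherits(runs, "chains_run")) runs <- list(runs)
  lapply(runs, function(r) if (inherits(r, "chains_run")) r$phases else r)
}

label_series <- function(runs) {
  if (inherits(runs, "chains_condition")) runs <- runs$runs
  if (inherits(runs, "chains_run")) runs <- list(runs)
  lapply(runs, function(r) r$labels)
}

#' First-phase statistics
#'
#' The first phase is the first classified (non-"none") percept of each
#' run; its choice and duration behave qualitatively differently from the
#' ongoing switching, so they are analysed separately.  Integrated and
#' segregated first phases are pooled for the duration average.
#'
#' @param runs a `chains_condition`, a list of `chains_run` objects, or a
#'   list of phase tables as returned by [extract_phases()].
#' @return list with `fraction_segregated_first`, `mean_first_phase_s`,
#'   `first_labels`, `first_durations_s`, `latency_s` (time to the first
#'   classified percept) and `n_empty` (runs without any phase, excluded).
#' @export
first_phase_stats <- function(runs) {
  pts <- phase_tables(runs)
  empty <- vapply(pts, function(p) nrow(p) == 0, TRUE)
  firsts <- lapply(pts[!empty], function(p) p[1, ])
  labs <- vapply(firsts, function(p) p$label, "")
  durs <- vapply(firsts, function(p) p$duration_ms, 0) / 1000
  lats <- vapply(firsts, function(p) p$start_ms, 0) / 1000
  list(fraction_segregated_first = mean(labs == "segregated"),
       mean_first_phase_s = mean(durs),
       first_labels = labs,
       first_durations_s = durs,
       latency_s = lats,
       n_empty = sum(empty))
}

#' Statistics of the phases after the first
#'
#' Time-weighted proportion of the segregated percept and mean phase
#' duration, with the first phase of every run excluded.  Runs without any
#' subsequent phase receive the run-set averages in their place (the same
#' missing-data rule applied to participants without subsequent reports).
#'
#' @inheritParams first_phase_stats
#' @return list with `prop_segregated` (time-weighted, averaged over
#'   runs), `mean_duration_s`, per-run vectors, and `n_imputed`.
#' @export
subsequent_phase_stats <- function(runs) {
  pts <- phase_tables(runs)
  subs <- lapply(pts, function(p) if (nrow(p) > 1) p[-1, ] else p[0, ])
  has <- vapply(subs, nrow, 0L) > 0
  prop <- vapply(subs, function(p) {
    if (!nrow(p)) return(NA_real_)
    sum(p$duration_ms[p$label == "segregated"]) / sum(p$duration_ms)
  }, 0)
  mdur <- vapply(subs, function(p) {
    if (!nrow(p)) return(NA_real_)
    mean(p$duration_ms) / 1000
  }, 0)
  n_imp <- sum(!has)
  if (any(has) && n_imp) {
    prop[!has] <- mean(prop[has])
    mdur[!has] <- mean(mdur[has])
  }
  list(prop_segregated = mean(prop), mean_duration_s = mean(mdur),
       per_run_prop = prop, per_run_duration_s = mdur, n_imputed = n_imp)
}

#' Time course of the probability of segregation
#'
#' The pointwise fraction of runs reporting segregation, smoothed with a
#' centred moving average (2-s window by default), as used for the
#' classical "build-up of streaming" curves.  At the stimulus onset the
#' probability is always zero because no pattern has been discovered yet.
#'
#' @inheritParams first_phase_stats
#' @param dt_ms label sampling interval in ms (default 10, the trace
#'   decimation of [chains_run()]).
#' @param window_s smoothing window in seconds. Default 2.
#' @return data frame with `time_s` and `p_segregated`.
#' @export
segregation_time_course <- function(runs, dt_ms = 10, window_s = 2) {
  ls <- label_series(runs)
  if (!length(ls)) stop("no runs")
  n <- min(lengths(ls))
  seg <- vapply(ls, function(x) as.numeric(x[seq_len(n)] == 2L), numeric(n))
  p <- rowMeans(seg)
  ## centred moving average; partial windows at the edges
  half <- max(1, round(window_s * 1000 / dt_ms / 2))
  cs <- cumsum(c(0, p))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  data.frame(time_s = seq_len(n) * dt_ms / 1000, p_segregated = sm)
}

#' Log-normality of phase durations
#'
#' Shapiro-Wilk test applied to the logarithms of phase durations (in
#' ms): under log-normality W is close to 1.
#'
#' @param durations_ms numeric vector of phase durations in ms.
#' @return list with `W`, `p_value`, `n` and `flag` (`"ok"`, `"too_few"`
#'   for n < 3, or `"degenerate"` when all durations are identical).
#' @export
lognormality_test <- function(durations_ms) {
  n <- length(durations_ms)
  if (n < 3)
    return(list(W = NA_real_, p_value = NA_real_, n = n, flag = "too_few"))
  if (length(unique(durations_ms)) == 1)
    return(list(W = NA_real_, p_value = NA_real_, n = n, flag = "degenerate"))
  s <- stats::shapiro.test(log(durations_ms))
  list(W = unname(s$statistic), p_value = s$p.value, n = n, flag = "ok")
}

#' Histogram of phase durations
#'
#' @param durations_ms phase durations in ms.
#' @param bin_width_ms bin width in ms.
#' @param max_ms upper edge; defaults to the smallest multiple of
#'   `bin_width_ms` covering the data.
#' @return data frame with `bin_lo_ms`, `bin_hi_ms`, `count`.
#' @export
phase_histogram <- function(durations_ms, bin_width_ms = 5000,
                            max_ms = NULL) {
  if (is.null(max_ms))
    max_ms <- if (length(durations_ms))
      bin_width_ms * ceiling(max(durations_ms) / bin_width_ms)
    else bin_width_ms
  breaks <- seq(0, max_ms, by = bin_width_ms)
  counts <- if (length(durations_ms))
    graphics::hist(durations_ms, breaks = breaks, plot = FALSE,
                   right = FALSE)$counts
  else integer(length(breaks) - 1)
  data.frame(bin_lo_ms = breaks[-length(breaks)], bin_hi_ms = breaks[-1],
             count = counts)
}

#' Pooled phase durations of a set of runs
#'
#' @inheritParams first_phase_stats
#' @param subsequent_only drop each run's first phase.
#' @return numeric vector of durations in ms.
#' @export
pooled_durations <- function(runs, subsequent_only = FALSE) {
  pts <- phase_tables(runs)
  unlist(lapply(pts, function(p) {
    if (subsequent_only && nrow(p)) p <- p[-1, ]
    p$duration_ms
  }), use.names = FALSE)
}

#' Proportion of classified time spent segregated
#'
#' Segregated time as a fraction of all classified (integrated +
#' segregated) time, from the phase table of one or several runs.
#'
#' @inheritParams first_phase_stats
#' @return fraction in `[0, 1]`.
#' @export
dominance_segregated <- function(runs) {
  pts <- phase_tables(runs)
  seg <- sum(vapply(pts, function(p)
    sum(p$duration_ms[p$label == "segregated"]), 0))
  tot <- sum(vapply(pts, function(p) sum(p$duration_ms), 0))
  seg / tot
}

#' Summarise a simulated condition
#'
#' Bundles the quantities reported per stimulus condition: first-phase
#' choice and duration, subsequent-phase dominance and mean duration, the
#' segregation time course, pooled durations and the log-normality check.
#'
#' @param cond a `chains_condition` (or list of runs with labels kept).
#' @return list of class `condition_summary`.
#' @export
condition_summary <- function(cond) {
  fp <- first_phase_stats(cond)
  sp <- subsequent_phase_stats(cond)
  tc <- segregation_time_course(cond)
  dur <- pooled_durations(cond)
  out <- list(condition = if (inherits(cond, "chains_condition"))
                cond$condition else NULL,
              n_runs = length(phase_tables(cond)),
              first_segregated_fraction = fp$fraction_segregated_first,
              mean_first_phase_s = fp$mean_first_phase_s,
              subsequent_segregated_proportion = sp$prop_segregated,
              mean_subsequent_phase_s = sp$mean_duration_s,
              dominance_segregated = dominance_segregated(cond),
              n_phases = length(dur),
              mean_phase_s = mean(dur) / 1000,
              lognormality = lognormality_test(dur),
              time_course = tc)
  class(out) <- "condition_summary"
  out
}

#' Write a condition summary as JSON
#'
#' @param x a `condition_summary`.
#' @param path output file.
#' @param time_course include the (long) time-course vector.
#' @return `path`, invisibly.
#' @export
write_condition_json <- function(x, path, time_course = FALSE) {
  y <- unclass(x)
  if (!time_course) y$time_course <- NULL
  jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
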