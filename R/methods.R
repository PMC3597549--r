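#' @export
print.chains_run <- function(x, ...) {
  cc <- x$condition
  cat(sprintf("<chains_run: %s, %.0f s, seed %d>\n",
              if (cc$custom_events) "custom event sequence"
              else sprintf("ABA- train, df = %g ST, dt = %g ms",
                           cc$delta_f, cc$delta_t),
              cc$duration_s, x$seed))
  comp <- x$chains[x$chains$status %in% c("competitive"), , drop = FALSE]
  cat(sprintf("  chains: %d closed, %d entered competition\n",
              nrow(x$chains), nrow(comp)))
  if (nrow(x$phases)) {
    cat(sprintf("  phases: %d (first: %s at %.1f s); segregated %.0f%% of classified time\n",
                nrow(x$phases), x$phases$label[1], x$phases$start_ms[1] / 1000,
                100 * dominance_segregated(x)))
  } else cat("  phases: none classified\n")
  invisible(x)
}

#' @export
summary.chains_run <- function(object, ...) {
  x <- object
  comp <- x$chains[x$chains$status == "competitive", , drop = FALSE]
  out <- list(condition = x$condition, seed = x$seed,
              n_chains_closed = nrow(x$chains),
              n_competitive = nrow(comp),
              competitive = comp,
              phases = x$phases,
              dominance_segregated = if (nrow(x$phases))
                dominance_segregated(x) else NA_real_,
              mean_phase_s = if (nrow(x$phases))
                mean(x$phases$duration_ms) / 1000 else NA_real_)
  class(out) <- "summary.chains_run"
  out
}

#' @export
print.summary.chains_run <- function(x, ...) {
  cat(sprintf("Run summary (seed %d): %d chains closed, %d competitive\n",
              x$seed, x$n_chains_closed, x$n_competitive))
  if (!is.na(x$dominance_segregated))
    cat(sprintf("Segregated %.0f%% of classified time; mean phase %.1f s\n",
                100 * x$dominance_segregated, x$mean_phase_s))
  cat("\nCompetitive chains:\n"); print(x$competitive)
  cat("\nPhases:\n"); print(x$phases)
  invisible(x)
}

#' Plot a simulated trial
#'
#' Top panel: the percept track (integrated/segregated).  Bottom panel:
#' low-pass filtered excitations of the competitive chains (blue:
#' integrated chain; red/orange: single-frequency chains).
#'
#' @param x a `chains_run` with traces kept.
#' @param ... ignored.
#' @export
plot.chains_run <- function(x, ...) {
  if (is.null(x$traces)) stop("run was simulated with keep_traces = FALSE")
  ef <- x$traces$E_filt
  t_s <- x$label_times_ms / 1000
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(t_s, x$labels, type = "n", ylim = c(0.5, 2.5),
                 yaxt = "n", ylab = "percept", xlab = "")
  graphics::axis(2, at = c(1, 2), labels = c("int", "seg"), las = 1)
  graphics::points(t_s[x$labels == 1L], rep(1, sum(x$labels == 1L)),
                   pch = ".", col = "blue")
  graphics::points(t_s[x$labels == 2L], rep(2, sum(x$labels == 2L)),
                   pch = ".", col = "red")
  graphics::matplot(t_s, ef, type = "l", lty = 1,
                    col = ifelse(x$meta$both_class, "blue", "red"),
                    xlab = "time (s)", ylab = "filtered E")
  invisible(x)
}

#' @export
print.chains_condition <- function(x, ...) {
  cat(sprintf("<chains_condition: df = %g ST, dt = %g ms, %d runs x %.0f s>\n",
              x$condition$delta_f, x$condition$delta_t,
              x$condition$n_runs, x$condition$duration_s))
  s <- condition_summary(x)
  cat(sprintf("  segregated first: %.0f%% of runs; mean first phase %.1f s\n",
              100 * s$first_segregated_fraction, s$mean_first_phase_s))
  cat(sprintf("  subsequent: segregated %.0f%% of time, mean phase %.1f s; %d phases pooled\n",
              100 * s$subsequent_segregated_proportion,
              s$mean_subsequent_phase_s, s$n_phases))
  invisible(x)
}

#' @export
summary.chains_condition <- function(object, ...) condition_summary(object)

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary>\n")
  flat <- x[c("n_runs", "first_segregated_fraction", "mean_first_phase_s",
              "subsequent_segregated_proportion", "mean_subsequent_phase_s",
              "dominance_segregated", "n_phases", "mean_phase_s")]
  for (n in names(flat)) cat(sprintf("  %-34s %s\n", n,
                                     format(flat[[n]], digits = 4)))
  if (x$lognormality$flag == "ok")
    cat(sprintf("  %-34s %.3f (p = %.3f, n = %d)\n", "Shapiro-Wilk W(log dur)",
                x$lognormality$W, x$lognormality$p_value, x$lognormality$n))
  invisible(x)
}

#' @export
print.chains_grid <- function(x, ...) {
  cat(sprintf("<chains_grid: %d conditions x %d runs>\n",
              nrow(x$grid), x$n_runs))
  cat("\nProportion segregated (subsequent phases):\n")
  print(round(grid_matrix(x, "subsequent_segregated_proportion"), 2))
  invisible(x)
}

#' Plot the time course of segregation probability
#'
#' @param x a `chains_condition`.
#' @param ... ignored.
#' @export
plot.chains_condition <- function(x, ...) {
  tc <- segregation_time_course(x)
  graphics::plot(tc$time_s, tc$p_segregated, type = "l", ylim = c(0, 1),
                 xlab = "time (s)", ylab = "P(segregated)")
  invisible(x)
}
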