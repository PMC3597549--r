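#' Simulate repeated trials of one stimulus condition
#'
#' Runs `n_runs` independent trials (different noise and discovery seeds
#' derived from `seed`) of the same Δf/Δt condition, the simulation
#' analogue of a group of listeners hearing one 4-minute train each.
#'
#' @inheritParams chains_run
#' @param n_runs number of repeats. Default 15.
#' @param keep_traces keep the full state traces of every run (memory
#'   heavy); phase tables, labels and chain logs are always kept.
#' @param ... further arguments passed to [chains_run()].
#' @return An object of class `chains_condition`: list with `runs`,
#'   `condition`, `seeds`.
#' @export
chains_condition <- function(delta_f = 16, delta_t = 200, duration_s = 240,
                             n_runs = 15, seed = 1, keep_traces = FALSE,
                             ...) {
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    r <- chains_run(delta_f, delta_t, duration_s, seed = run_seeds[i],
                    keep_traces = keep_traces, ...)
    runs[[i]] <- r
  }
  structure(list(runs = runs,
                 condition = list(delta_f = delta_f, delta_t = delta_t,
                                  duration_s = duration_s, n_runs = n_runs),
                 seeds = run_seeds, root_seed = seed),
            class = "chains_condition")
}

#' Sweep a grid of stimulus conditions
#'
#' Simulates `n_runs` trials for every combination of the frequency
#' separations and onset intervals, and summarises each condition.  With
#' `out_dir` set, per-condition phase tables (CSV), summaries (JSON) and a
#' manifest with all seeds and parameters are written; conditions whose
#' summary file already exists are skipped when `resume = TRUE`.
#'
#' @inheritParams chains_condition
#' @param delta_f_values,delta_t_values grid axes (semitones, ms).
#' @param out_dir optional output directory.
#' @param resume skip conditions already present in `out_dir`.
#' @param ... passed to [chains_run()].
#' @return An object of class `chains_grid`: list of condition summaries
#'   plus the grid layout.
#' @export
chains_grid <- function(delta_f_values = c(4, 10, 16, 22),
                        delta_t_values = c(100, 150, 200, 250),
                        duration_s = 240, n_runs = 15, seed = 1,
                        out_dir = NULL, resume = FALSE, ...) {
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  }, add = TRUE)
  grid <- expand.grid(delta_f = delta_f_values, delta_t = delta_t_values)
  set.seed(seed)
  cond_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  summaries <- vector("list", nrow(grid))
  status <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tag <- sprintf("df%02d_dt%03d", grid$delta_f[i], grid$delta_t[i])
    jpath <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".json"))
    if (resume && !is.null(out_dir) && file.exists(jpath)) {
      status[i] <- "skipped"
      next
    }
    res <- tryCatch({
      cond <- chains_condition(grid$delta_f[i], grid$delta_t[i], duration_s,
                               n_runs, seed = cond_seeds[i], ...)
      s <- condition_summary(cond)
      if (!is.null(out_dir)) {
        write_condition_json(s, jpath)
        utils::write.csv(condition_phase_table(cond),
                         file.path(out_dir, paste0(tag, "_phases.csv")),
                         row.names = FALSE)
      }
      s
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- paste("failed:", conditionMessage(res))
    } else {
      summaries[[i]] <- res
      status[i] <- "ok"
    }
  }
  out <- structure(list(grid = grid, summaries = summaries, status = status,
                        n_runs = n_runs, duration_s = duration_s,
                        root_seed = seed, cond_seeds = cond_seeds),
                   class = "chains_grid")
  if (!is.null(out_dir)) {
    manifest <- list(root_seed = seed, cond_seeds = cond_seeds,
                     grid = grid, n_runs = n_runs, duration_s = duration_s,
                     status = status,
                     package_version = as.character(utils::packageVersion("streamchains")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    for (m in c("first_segregated_fraction", "mean_first_phase_s",
                "subsequent_segregated_proportion",
                "mean_subsequent_phase_s")) {
      utils::write.csv(grid_matrix(out, m),
                       file.path(out_dir, paste0("grid_", m, ".csv")))
    }
  }
  out
}

#' Tidy phase table of a condition
#'
#' One row per perceptual phase across all runs of a condition -- the
#' single artifact all further analyses consume.
#'
#' @param cond a `chains_condition`.
#' @return data frame with `run_id`, `delta_f`, `delta_t`, `phase_index`,
#'   `label`, `start_ms`, `end_ms`, `duration_ms`.
#' @export
condition_phase_table <- function(cond) {
  stopifnot(inherits(cond, "chains_condition"))
  do.call(rbind, lapply(seq_along(cond$runs), function(i) {
    p <- cond$runs[[i]]$phases
    if (!nrow(p)) return(NULL)
    data.frame(run_id = i, delta_f = cond$condition$delta_f,
               delta_t = cond$condition$delta_t,
               phase_index = seq_len(nrow(p)), p)
  }))
}

#' Arrange one summary quantity over the stimulus grid
#'
#' @param x a `chains_grid`.
#' @param what name of a scalar field of the condition summaries.
#' @return matrix with rows Δt and columns Δf.
#' @export
grid_matrix <- function(x, what = "subsequent_segregated_proportion") {
  stopifnot(inherits(x, "chains_grid"))
  dfv <- sort(unique(x$grid$delta_f)); dtv <- sort(unique(x$grid$delta_t))
  m <- matrix(NA_real_, length(dtv), length(dfv),
              dimnames = list(paste0("dt_", dtv), paste0("df_", dfv)))
  for (i in seq_len(nrow(x$grid))) {
    s <- x$summaries[[i]]
    if (is.null(s)) next
    m[match(x$grid$delta_t[i], dtv), match(x$grid$delta_f[i], dfv)] <-
      s[[what]]
  }
  m
}
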