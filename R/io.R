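#' Export the chain log as JSON lines
#'
#' One JSON object per line and per closed chain: id, cycle offsets (ms)
#' and frequencies (Hz), period, whether the chain entered the
#' competition, and its closure/admission/death times.  Useful for
#' debugging discovery and for building test fixtures.
#'
#' @param run a `chains_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain_log <- function(run, path) {
  stopifnot(inherits(run, "chains_run"))
  ch <- run$chains
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ch))) {
    rec <- as.list(ch[i, ])
    rec$competitive <- identical(rec$status, "competitive")
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' Export per-chain state traces as CSV
#'
#' Long-format table of the dynamical state variables (`E`, `I`, `A`,
#' `U`, `S`, `R`, `X`) of every competitive chain at the run's trace
#' decimation.
#'
#' @param run a `chains_run` simulated with `keep_traces = TRUE`.
#' @param path output file.
#' @param every write every `every`-th sample. Default 1.
#' @return `path`, invisibly.
#' @export
write_state_traces <- function(run, path, every = 1) {
  stopifnot(inherits(run, "chains_run"))
  if (is.null(run$traces)) stop("run was simulated with keep_traces = FALSE")
  idx <- seq(1, length(run$label_times_ms), by = every)
  out <- NULL
  for (j in seq_len(nrow(run$meta))) {
    d <- data.frame(time_ms = run$label_times_ms[idx],
                    chain_id = run$meta$id[j])
    for (v in DYN_VARS) d[[v]] <- run$traces[[v]][idx, j]
    out <- rbind(out, d[!is.na(d$E), ])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Save and load the model configuration
#'
#' Serialises the full parameter set (chain-building and dynamics) to a
#' single JSON block, and reads it back into parameter objects.
#'
#' @param assembly an [assembly_params()].
#' @param dynamics a [dynamics_params()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` a list
#'   with elements `assembly` and `dynamics`.
#' @export
write_config <- function(path, assembly = assembly_params(),
                         dynamics = dynamics_params()) {
  jsonlite::write_json(list(assembly = unclass(assembly),
                            dynamics = unclass(dynamics)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- cfg$assembly
  if (!is.null(a) && is.null(a$max_open_span)) a["max_open_span"] <- list(NULL)
  list(assembly = do.call(assembly_params, a %||% list()),
       dynamics = do.call(dynamics_params, cfg$dynamics %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
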