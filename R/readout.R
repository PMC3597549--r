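#' Map chain excitations to a categorical percept
#'
#' The model analogue of the two-button forced choice used in streaming
#' experiments.  Excitation traces are first low-pass filtered (first-order
#' exponential smoother) to suppress the per-event ripple that the rate
#' estimators imprint on `E`; the percept at each sample is then
#' *integrated* when the filtered excitation of the integrated chain (a
#' chain predicting both frequency classes) exceeds that of every
#' single-frequency chain, *segregated* when some single-frequency chain
#' beats the integrated chain (or when no integrated chain is competitive
#' while a single-frequency chain is), and *none* while no chain is
#' competitive.  Exact ties keep the previous label.
#'
#' @param e_filt matrix of low-pass filtered excitations (samples x
#'   chains); `NA` where a chain is not (yet) competitive.
#' @param both_class logical vector, one per column: does the chain predict
#'   more than one frequency class?
#' @return integer vector of labels: 0 none, 1 integrated, 2 segregated.
#' @export
classify_percept <- function(e_filt, both_class) {
  stopifnot(ncol(e_filt) == length(both_class))
  n <- nrow(e_filt)
  out <- integer(n)
  prev <- 0L
  ib <- which(both_class); is_ <- which(!both_class)
  for (t in seq_len(n)) {
    ei <- suppressWarnings(max(e_filt[t, ib], na.rm = TRUE))
    es <- suppressWarnings(max(e_filt[t, is_], na.rm = TRUE))
    lab <- if (ei == -Inf && es == -Inf) 0L
    else if (es == -Inf) 1L
    else if (ei == -Inf) 2L
    else if (ei > es) 1L
    else if (es > ei) 2L
    else prev
    out[t] <- lab
    prev <- lab
  }
  out
}

#' First-order low-pass filter for excitation traces
#'
#' @param x numeric matrix (samples x chains), `NA` before a chain exists.
#' @param dt_ms sample spacing in ms.
#' @param tau_ms filter time constant in ms (default 500).
#' @return filtered matrix of the same shape; each chain's filter starts at
#'   zero when the chain first appears.
#' @export
lowpass <- function(x, dt_ms, tau_ms = 500) {
  a <- 1 - exp(-dt_ms / tau_ms)
  apply_col <- function(v) {
    out <- v
    i0 <- which(!is.na(v))
    if (!length(i0)) return(out)
    acc <- 0
    for (t in i0[1]:length(v)) {
      xv <- v[t]
      if (is.na(xv)) xv <- 0
      acc <- acc + a * (xv - acc)
      out[t] <- acc
    }
    out
  }
  if (is.null(dim(x))) return(apply_col(x))
  apply(x, 2, apply_col)
}

#' Extract perceptual phases from a label time series
#'
#' A phase is a maximal stretch of one percept.  Mirroring the treatment of
#' human button presses, runs shorter than `min_duration_ms` are discarded
#' and absorbed into their neighbours (they are taken to be response
#' bounce, not conscious percepts), and "none" stretches are excluded from
#' the phase table.
#'
#' @param labels integer labels (0 none, 1 integrated, 2 segregated).
#' @param dt_ms sample spacing in ms.
#' @param min_duration_ms minimum phase duration; shorter runs are
#'   absorbed. Default 300. Set to 0 to disable the discard.
#' @return data frame with columns `label` ("integrated"/"segregated"),
#'   `start_ms`, `end_ms`, `duration_ms`.
#' @export
extract_phases <- function(labels, dt_ms, min_duration_ms = 300) {
  stopifnot(length(labels) > 0)
  r <- rle(as.integer(labels))
  runs <- data.frame(label = r$values, len = r$lengths)
  min_len <- min_duration_ms / dt_ms
  repeat {
    ## merge adjacent equal labels
    if (nrow(runs) > 1) {
      same <- c(FALSE, runs$label[-1] == runs$label[-nrow(runs)])
      if (any(same)) {
        grp <- cumsum(!same)
        runs <- data.frame(label = runs$label[!same],
                           len = as.vector(tapply(runs$len, grp, sum)))
      }
    }
    short <- which(runs$label != 0L & runs$len < min_len)
    if (!length(short)) break
    i <- short[which.min(runs$len[short])]
    prev_ok <- i > 1 && runs$label[i - 1] != 0L
    next_ok <- i < nrow(runs) && runs$label[i + 1] != 0L
    if (prev_ok && next_ok) {
      if (runs$label[i - 1] == runs$label[i + 1]) {
        runs$label[i] <- runs$label[i - 1]
      } else if (runs$len[i - 1] >= runs$len[i + 1]) {
        runs$label[i] <- runs$label[i - 1]
      } else runs$label[i] <- runs$label[i + 1]
    } else if (prev_ok) {
      runs$label[i] <- runs$label[i - 1]
    } else if (next_ok) {
      runs$label[i] <- runs$label[i + 1]
    } else {
      runs$label[i] <- 0L
    }
  }
  ends <- cumsum(runs$len)
  starts <- c(0, ends[-length(ends)])
  keep <- runs$label != 0L
  data.frame(label = c("none", "integrated", "segregated")[runs$label[keep] + 1L],
             start_ms = starts[keep] * dt_ms,
             end_ms = ends[keep] * dt_ms,
             duration_ms = runs$len[keep] * dt_ms)
}
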