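#' Tone-event sequences
#'
#' An event sequence is the symbolic input to the model: a set of discrete
#' tone onsets, each carrying an onset time (ms), a frequency (Hz) and a
#' nominal tone duration (ms).  The model is onset-based -- predictions are
#' made and evaluated at event onsets -- so the duration is carried for
#' completeness but plays no role in chain building or competition.
#'
#' @param onset_ms numeric vector of onset times in ms (non-negative).
#' @param frequency_hz numeric vector of tone frequencies in Hz (positive).
#' @param duration_ms tone duration(s) in ms; recycled. Default 75.
#' @param total_duration_ms total duration of the sequence in ms; defaults
#'   to the last onset plus one tone duration.
#' @return A data frame of class `event_sequence` with columns `onset_ms`,
#'   `frequency_hz`, `duration_ms`, ordered by onset, and an attribute
#'   `total_duration_ms`.
#' @examples
#' event_sequence(c(0, 100, 200), c(400, 1008, 400))
#' @export
event_sequence <- function(onset_ms, frequency_hz, duration_ms = 75,
                           total_duration_ms = NULL) {
  if (length(onset_ms) != length(frequency_hz))
    stop("onset_ms and frequency_hz must have the same length")
  if (any(!is.finite(onset_ms)) || any(onset_ms < 0))
    stop("onsets must be finite and non-negative")
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0))
    stop("frequencies must be finite and positive")
  duration_ms <- rep_len(duration_ms, length(onset_ms))
  ord <- order(onset_ms, frequency_hz)
  x <- data.frame(onset_ms = onset_ms[ord],
                  frequency_hz = frequency_hz[ord],
                  duration_ms = duration_ms[ord])
  if (anyDuplicated(x[c("onset_ms", "frequency_hz")]))
    stop("duplicate (onset, frequency) pairs are not allowed")
  if (any(diff(x$onset_ms) < 0)) stop("onsets must be ordered") # unreachable
  if (is.null(total_duration_ms))
    total_duration_ms <- if (nrow(x)) max(x$onset_ms) + x$duration_ms[nrow(x)] else 0
  if (nrow(x) && any(x$onset_ms >= total_duration_ms))
    stop("all onsets must fall before total_duration_ms")
  attr(x, "total_duration_ms") <- total_duration_ms
  class(x) <- c("event_sequence", "data.frame")
  x
}

#' Frequency distance in semitones
#'
#' Distance between two pure-tone frequencies on the logarithmic musical
#' scale: 12 semitones per doubling of frequency.  Symmetric and
#' non-negative; additive along the log-frequency axis.
#'
#' @param f1,f2 frequencies in Hz (positive); vectorised.
#' @return distance(s) in semitones.
#' @examples
#' semitone_distance(400, 800)  # one octave = 12 ST
#' @export
semitone_distance <- function(f1, f2) {
  if (any(!is.finite(f1)) || any(!is.finite(f2)) || any(f1 <= 0) || any(f2 <= 0))
    stop("frequencies must be finite and positive")
  abs(12 * log2(f1 / f2))
}

#' Generate an ABA- galloping tone train
#'
#' Builds the isochronous ABA- stimulus used in auditory streaming
#' experiments: a repeating four-slot cycle of length `4 * delta_t` ms
#' holding a low tone A at offset 0, a high tone B at `delta_t`, another A
#' at `2 * delta_t`, and silence in the fourth slot.  The A frequency is
#' `base_frequency_hz`; B lies `delta_f` semitones above A.  Only whole
#' events with onset strictly before the requested duration are emitted, so
#' a trailing partial cycle is truncated at whole tones.
#'
#' @param delta_f frequency separation between A and B in semitones.
#' @param delta_t onset-to-onset interval in ms (> 0).
#' @param duration_s total stimulus duration in seconds (>= 0). Default 240.
#' @param base_frequency_hz frequency of the A tones in Hz. Default 400.
#' @param tone_ms tone duration in ms. Default 75.
#' @return An [event_sequence()].
#' @examples
#' tr <- aba_train(16, 200, duration_s = 4.8)
#' nrow(tr)  # 3 tones per 800-ms cycle
#' @export
aba_train <- function(delta_f, delta_t, duration_s = 240,
                      base_frequency_hz = 400, tone_ms = 75) {
  stopifnot(is.finite(delta_f), is.finite(delta_t), delta_t > 0,
            is.finite(duration_s), duration_s >= 0,
            is.finite(base_frequency_hz), base_frequency_hz > 0)
  dur_ms <- duration_s * 1000
  f_b <- base_frequency_hz * 2^(delta_f / 12)
  n_cycles <- ceiling(dur_ms / (4 * delta_t))
  if (n_cycles == 0)
    return(event_sequence(numeric(0), numeric(0), tone_ms, dur_ms))
  cyc <- 4 * delta_t * (seq_len(n_cycles) - 1)
  onset <- c(outer(c(0, delta_t, 2 * delta_t), cyc, `+`))
  freq <- rep_len(c(base_frequency_hz, f_b, base_frequency_hz), length(onset))
  keep <- onset < dur_ms
  event_sequence(onset[keep], freq[keep], tone_ms, max(dur_ms, 1e-9))
}

#' Read and write event sequences as CSV
#'
#' The on-disk dialect has columns `onset_ms`, `frequency_hz`,
#' `duration_ms`, so arbitrary repetitive patterns (for instance an ABAC
#' sequence) can be scripted outside R and fed to the simulator.
#'
#' @param x an [event_sequence()].
#' @param path file path.
#' @param total_duration_ms optional total duration override when reading.
#' @return `read_events` returns an [event_sequence()];
#'   `write_events` returns `path` invisibly.
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "event_sequence"))
  utils::write.csv(as.data.frame(x)[c("onset_ms", "frequency_hz", "duration_ms")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, total_duration_ms = NULL) {
  d <- utils::read.csv(path)
  need <- c("onset_ms", "frequency_hz")
  if (!all(need %in% names(d)))
    stop("CSV must contain columns onset_ms and frequency_hz")
  dur <- if ("duration_ms" %in% names(d)) d$duration_ms else 75
  event_sequence(d$onset_ms, d$frequency_hz, dur, total_duration_ms)
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence: %d events over %.0f ms", nrow(x),
              attr(x, "total_duration_ms")))
  if (nrow(x))
    cat(sprintf(", %d distinct frequencies", length(unique(x$frequency_hz))))
  cat(">\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
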