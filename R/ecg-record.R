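#' Sampled single-lead ECG record
#'
#' Container for a uniformly sampled single-lead ECG trace in millivolts.
#'
#' @param samples numeric vector of sample values in mV; at least 2 finite
#'   values.
#' @param fs sampling rate in Hz, positive.
#' @param id record identifier.
#' @param lead lead name.
#' @return An object of class `ecg_record` with fields `samples`, `fs`,
#'   `id`, `lead`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 5 * (0:719) / 360), fs = 360)
#' rec
#' @export
ecg_record <- function(samples, fs, id = "record", lead = "MLII") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("an ECG record needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples))) stop("all samples must be finite", call. = FALSE)
  stop_if_not_scalar(fs, "fs")
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  structure(list(samples = samples, fs = fs,
                 id = as.character(id)[1], lead = as.character(lead)[1]),
            class = "ecg_record")
}

is_ecg_record <- function(x) inherits(x, "ecg_record")

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> '%s' lead %s: %d samples at %g Hz (%.1f s)\n",
              x$id, x$lead, length(x$samples), x$fs, length(x$samples) / x$fs))
  cat(sprintf("  amplitude range [%.3f, %.3f] mV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Sample times of a record
#'
#' @param record an [ecg_record()].
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
record_times <- function(record) {
  stopifnot(is_ecg_record(record))
  (seq_along(record$samples) - 1) / record$fs
}
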