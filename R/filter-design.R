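#' Design a digital Butterworth band-pass or band-stop filter
#'
#' Thin wrapper over [signal::butter()] that returns a digital
#' [transfer_function()]. `order` is the analog prototype order, so the
#' resulting band filter has polynomial degree `2 * order`. Band edges sit at
#' the usual -3 dB points.
#'
#' @param kind `"pass"` or `"stop"`.
#' @param f_low,f_high band edges in Hz, `0 < f_low < f_high < fs/2`.
#' @param order prototype order, at least 1.
#' @param fs sampling rate, Hz.
#' @return a digital [transfer_function()].
#' @examples
#' bp <- design_butterworth("pass", 5, 15, order = 2, fs = 360)
#' Mod(evaluate_response(bp, c(5, sqrt(75), 15)))
#' @export
design_butterworth <- function(kind = c("pass", "stop"), f_low, f_high, order, fs) {
  kind <- match.arg(kind)
  stop_if_not_scalar(f_low, "f_low"); stop_if_not_scalar(f_high, "f_high")
  stop_if_not_scalar(fs, "fs")
  if (order < 1) stop("'order' must be at least 1", call. = FALSE)
  if (!(f_low > 0 && f_low < f_high)) {
    stop("band edges must satisfy 0 < f_low < f_high", call. = FALSE)
  }
  if (f_high >= fs / 2) {
    stop("band edges must lie below the Nyquist rate fs/2", call. = FALSE)
  }
  ba <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = kind)
  transfer_function(ba$b, ba$a, domain = "z", fs = fs)
}

#' Design a digital Butterworth low-pass filter
#'
#' Used for the optional smoothing stage that caps the signal band (e.g. a
#' 150 Hz corner when the sampling rate allows it).
#'
#' @param f_cut corner frequency in Hz, below Nyquist.
#' @param order filter order, at least 1.
#' @param fs sampling rate, Hz.
#' @return a digital [transfer_function()].
#' @export
design_lowpass <- function(f_cut, order, fs) {
  stop_if_not_scalar(f_cut, "f_cut"); stop_if_not_scalar(fs, "fs")
  if (order < 1) stop("'order' must be at least 1", call. = FALSE)
  if (f_cut <= 0 || f_cut >= fs / 2) {
    stop("'f_cut' must lie in (0, fs/2)", call. = FALSE)
  }
  ba <- signal::butter(order, f_cut / (fs / 2), type = "low")
  transfer_function(ba$b, ba$a, domain = "z", fs = fs)
}

#' Design a linear-phase FIR filter
#'
#' Two kinds are provided, matching the two FIR preprocessing stages:
#'
#' * `"highpass"`: a DC-blocking baseline-wander filter built as an
#'   identity impulse minus a unit-DC-gain baseline estimator, so its DC
#'   gain is exactly zero. When the requested cutoff is resolvable at the
#'   given length (cutoff >= `2 * fs / order`), the estimator is a plain
#'   Hamming-windowed low-pass. At baseline-removal settings the cutoff sits
#'   far below the length-limited resolution (a 61-tap filter at 360 Hz
#'   resolves ~6 Hz, not 0.5 Hz); a short smoother would then track the QRS
#'   complex itself and clip the R wave, so the estimator instead averages
#'   only samples outside a central guard interval (`guard`, default 0.06 s,
#'   about a QRS half-width) — the short-filter analogue of estimating the
#'   baseline between beats. Requires an even order.
#' * `"bandstop"`: a Hamming-windowed band-stop via [signal::fir1()], used
#'   for power-line removal.
#'
#' Both designs are symmetric (linear phase) with `order + 1` coefficients
#' and a group delay of `order / 2` samples.
#'
#' @param kind `"highpass"` or `"bandstop"`.
#' @param cutoff one corner frequency (highpass) or two band edges
#'   (bandstop), Hz, all below Nyquist.
#' @param order filter order (number of taps minus one), at least 2.
#' @param fs sampling rate, Hz.
#' @param guard half-width in seconds of the central interval the guarded
#'   baseline estimator excludes (highpass with sub-resolution cutoff only).
#' @return a digital FIR [transfer_function()].
#' @export
design_fir <- function(kind = c("highpass", "bandstop"), cutoff, order, fs,
                       guard = 0.06) {
  kind <- match.arg(kind)
  stop_if_not_scalar(fs, "fs")
  if (order < 2) stop("'order' must be at least 2", call. = FALSE)
  cutoff <- as.numeric(cutoff)
  if (any(cutoff <= 0) || any(cutoff >= fs / 2)) {
    stop("cutoff frequencies must lie in (0, fs/2)", call. = FALSE)
  }
  if (kind == "highpass") {
    if (length(cutoff) != 1L) stop("highpass takes a single cutoff", call. = FALSE)
    if (order %% 2 != 0) stop("highpass requires an even order", call. = FALSE)
    half <- order / 2
    if (cutoff >= 2 * fs / order) {
      g <- signal::fir1(order, cutoff / (fs / 2), type = "low")
      g <- g / sum(g)            # unit DC gain smoother
    } else {
      # guarded baseline estimator: Hamming-weighted average of samples at
      # lags beyond the guard interval, zero inside it
      gs <- min(round(guard * fs), floor(0.7 * half))
      lags <- -half:half
      w <- 0.54 + 0.46 * cos(pi * lags / half)   # Hamming taper over the span
      w[abs(lags) <= gs] <- 0
      g <- w / sum(w)
    }
    h <- -g
    h[half + 1] <- h[half + 1] + 1
  } else {
    if (length(cutoff) != 2L || cutoff[1] >= cutoff[2]) {
      stop("bandstop takes increasing band edges c(f_low, f_high)", call. = FALSE)
    }
    h <- signal::fir1(order, cutoff / (fs / 2), type = "stop")
  }
  transfer_function(as.numeric(h), 1, domain = "z", fs = fs)
}

#' Two-stage Butterworth IIR cascade
#'
#' The series connection of a QRS-emphasis band-pass and a mains band-stop
#' Butterworth stage. With the defaults (band-pass 5-15 Hz of order 2,
#' band-stop 49-51 Hz of order 6) the cascade is a stable 16th-order digital
#' IIR filter — the high-order prototype that the minimax order-reduction
#' stage condenses.
#'
#' @param fs sampling rate, Hz.
#' @param f_low,f_high pass-band edges, Hz.
#' @param pass_order band-pass prototype order.
#' @param f_stop_low,f_stop_high stop-band edges, Hz.
#' @param stop_order band-stop prototype order.
#' @return a digital [transfer_function()] of order
#'   `2 * (pass_order + stop_order)`.
#' @export
design_iir_cascade <- function(fs = 360, f_low = 5, f_high = 15, pass_order = 2,
                               f_stop_low = 49, f_stop_high = 51, stop_order = 6) {
  bp <- design_butterworth("pass", f_low, f_high, pass_order, fs)
  bs <- design_butterworth("stop", f_stop_low, f_stop_high, stop_order, fs)
  cascade(bp, bs)
}

#' Apply a digital filter to an ECG record
#'
#' Forward-only filtering (the default) runs [signal::filter()] once and
#' therefore carries the filter's group delay; `zero_phase = TRUE` runs
#' forward-backward filtering ([signal::filtfilt()]), cancelling the delay
#' at the cost of squaring the magnitude response. Output length always
#' equals input length.
#'
#' @param tf a stable digital [transfer_function()] with the record's
#'   sampling rate.
#' @param record an [ecg_record()].
#' @param zero_phase logical; forward-backward filtering.
#' @return an [ecg_record()] of the filtered signal.
#' @export
apply_filter <- function(tf, record, zero_phase = FALSE) {
  stopifnot(is_transfer_function(tf), is_ecg_record(record))
  if (tf$domain != "z") {
    stop("analog transfer function: discretize with bilinear_tf() before filtering",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(tf$fs, record$fs))) {
    stop(sprintf("filter fs (%g) does not match record fs (%g)", tf$fs, record$fs),
         call. = FALSE)
  }
  if (!is_stable(tf)) stop("refusing to apply an unstable filter", call. = FALSE)
  x <- record$samples
  y <- if (zero_phase) {
    as.numeric(signal::filtfilt(signal::Arma(b = tf$num, a = tf$den), x))
  } else {
    as.numeric(signal::filter(signal::Arma(b = tf$num, a = tf$den), x))
  }
  ecg_record(y, fs = record$fs, id = record$id, lead = record$lead)
}

#' Compensate the group delay of a linear-phase FIR stage
#'
#' Shifts the signal left by `delay` samples, padding the tail with the last
#' value, so forward-only FIR output realigns with the input.
#'
#' @param x numeric signal.
#' @param delay delay in samples (an FIR of order N has delay N/2).
#' @return numeric vector, same length as `x`.
#' @export
compensate_delay <- function(x, delay) {
  delay <- as.integer(round(delay))
  if (delay <= 0) return(x)
  n <- length(x)
  if (delay >= n) return(rep(x[n], n))
  c(x[(delay + 1L):n], rep(x[n], delay))
}
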