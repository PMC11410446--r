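#' Hilbert envelope of a signal
#'
#' Computes the magnitude of the analytic signal `x + i H[x]`, where `H` is
#' the Hilbert transform (a 90-degree phase shifter). The analytic signal is
#' built in the frequency domain by zeroing negative frequencies and doubling
#' positive ones, the standard O(n log n) construction; the envelope
#' dominates the signal, `envelope >= |x|`, because the real part of the
#' analytic signal is `x` itself.
#'
#' @param x an [ecg_record()] or numeric vector with at least 8 samples.
#' @return numeric envelope, same length as the input.
#' @examples
#' t <- (0:3599) / 360
#' env <- hilbert_envelope(cos(2 * pi * 5 * t))  # ~= 1 away from the edges
#' @export
hilbert_envelope <- function(x) {
  if (is_ecg_record(x)) x <- x$samples
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("hilbert_envelope() needs at least 8 samples", call. = FALSE)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Detect R peaks on an envelope signal
#'
#' Scans the local maxima of a nonnegative envelope and keeps those
#' exceeding `threshold_fraction` times a running amplitude estimate. The
#' estimate starts at the largest envelope value of the first two seconds
#' and is updated after each accepted peak by an exponentially weighted
#' average (weight 0.125 per beat). Peaks closer than the refractory period
#' to the previous acceptance replace it when larger, otherwise they are
#' dropped, so detected peaks always respect the refractory spacing.
#'
#' @param envelope nonnegative numeric vector (e.g. from
#'   [hilbert_envelope()]).
#' @param fs sampling rate, Hz.
#' @param threshold_fraction fraction of the running amplitude estimate a
#'   local maximum must reach.
#' @param refractory minimum spacing between peaks, seconds.
#' @return integer vector of strictly increasing 1-based sample indices
#'   (empty for an all-zero envelope).
#' @export
detect_r_peaks <- function(envelope, fs, threshold_fraction = 0.5, refractory = 0.2) {
  envelope <- as.numeric(envelope)
  if (any(envelope < 0)) stop("'envelope' must be nonnegative", call. = FALSE)
  n <- length(envelope)
  if (n < 3L || all(envelope == 0)) return(integer(0))
  refr <- round(refractory * fs)
  left <- c(-Inf, envelope[-n])
  right <- c(envelope[-1], -Inf)
  cand <- which(envelope > left & envelope >= right & envelope > 0)
  level <- max(envelope[seq_len(min(n, round(2 * fs)))])
  peaks <- integer(0)
  for (i in cand) {
    if (envelope[i] < threshold_fraction * level) next
    if (length(peaks) && i - peaks[length(peaks)] < refr) {
      if (envelope[i] > envelope[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i
        level <- 0.875 * level + 0.125 * envelope[i]
      }
    } else {
      peaks <- c(peaks, i)
      level <- 0.875 * level + 0.125 * envelope[i]
    }
  }
  peaks
}

#' Locate Q and S troughs around detected R peaks
#'
#' Q is the signal minimum in the window before each R peak, S the minimum
#' in the window after it; the QRS interval is the Q-to-S time. Beats whose
#' windows would cross the record edge are dropped with a warning.
#'
#' @param record the [ecg_record()] the peaks refer to.
#' @param r_indices integer vector of R-peak sample indices, strictly
#'   increasing.
#' @param search_window one-sided search window in seconds (default 0.06 s,
#'   generous for a QRS half-width).
#' @return a [qrs_annotation()].
#' @export
locate_qs <- function(record, r_indices, search_window = 0.06) {
  stopifnot(is_ecg_record(record))
  r_indices <- as.integer(r_indices)
  if (length(r_indices) && any(diff(r_indices) <= 0L)) {
    stop("'r_indices' must be strictly increasing", call. = FALSE)
  }
  fs <- record$fs
  w <- round(search_window * fs)
  n <- length(record$samples)
  keep <- r_indices - w >= 1L & r_indices + w <= n
  if (any(!keep)) {
    warning(sprintf("%d beat(s) too close to the record edge were dropped", sum(!keep)))
  }
  r <- r_indices[keep]
  q <- s <- integer(length(r))
  for (k in seq_along(r)) {
    pre <- (r[k] - w):(r[k] - 1L)
    post <- (r[k] + 1L):(r[k] + w)
    q[k] <- pre[which.min(record$samples[pre])]
    s[k] <- post[which.min(record$samples[post])]
  }
  qrs_annotation(r = r, q = q, s = s, fs = fs, qrs = (s - q) / fs)
}

#' RR intervals from R-peak indices
#'
#' @param r_indices strictly increasing integer sample indices.
#' @param fs sampling rate, Hz.
#' @return numeric vector of successive R-to-R intervals in seconds (empty
#'   when fewer than 2 peaks). The mean heart rate is `60 / mean(rr)` bpm.
#' @export
rr_intervals <- function(r_indices, fs) {
  r_indices <- as.numeric(r_indices)
  if (length(r_indices) && any(diff(r_indices) <= 0)) {
    stop("'r_indices' must be strictly increasing", call. = FALSE)
  }
  if (length(r_indices) < 2L) return(numeric(0))
  diff(r_indices) / fs
}

#' Pan-Tompkins QRS detector
#'
#' The classic chain: 5-15 Hz band-pass (zero-phase Butterworth), five-point
#' derivative, squaring, 150 ms moving-window integration, then dual
#' adaptive signal/noise thresholds with a search-back pass for missed
#' beats. Detections are delay-compensated and refined to the local maximum
#' of the original signal, so returned indices refer to the input record.
#'
#' @param record an [ecg_record()] of at least 2 s at `fs >= 100` Hz.
#' @return integer vector of R-peak sample indices.
#' @export
pan_tompkins <- function(record) {
  stopifnot(is_ecg_record(record))
  fs <- record$fs
  if (fs < 100) stop("pan_tompkins() requires fs >= 100 Hz", call. = FALSE)
  n <- length(record$samples)
  if (n < 2 * fs) stop("record shorter than 2 s", call. = FALSE)
  x <- record$samples - mean(record$samples)
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, x))
  # five-point derivative, delay 2 samples
  d <- as.numeric(signal::filter(signal::Arma(b = c(2, 1, 0, -1, -2) / 8, a = 1), xf))
  sq <- d^2
  nw <- round(0.15 * fs)
  mwi <- as.numeric(signal::filter(signal::Arma(b = rep(1 / nw, nw), a = 1), sq))
  delay <- 2L + as.integer(floor((nw - 1) / 2))

  # candidate peaks of the integrated signal
  left <- c(-Inf, mwi[-n]); right <- c(mwi[-1], -Inf)
  cand <- which(mwi > left & mwi >= right)
  refr <- round(0.2 * fs)
  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr <- function() npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_recent <- numeric(0)
  last_cand_between <- function(a, b, level) {
    between <- cand[cand > a & cand < b & mwi[cand] > level]
    if (length(between)) between[which.max(mwi[between])] else NA_integer_
  }
  for (i in cand) {
    if (length(qrs) && i - qrs[length(qrs)] < refr) next
    if (mwi[i] > thr()) {
      # search-back first: did we miss a beat in an overlong RR gap?
      if (length(qrs) && length(rr_recent) >= 2) {
        rr_avg <- mean(tail(rr_recent, 8))
        if (i - qrs[length(qrs)] > 1.66 * rr_avg) {
          sb <- last_cand_between(qrs[length(qrs)] + refr, i - refr, 0.5 * thr())
          if (!is.na(sb)) {
            qrs <- c(qrs, sb)
            spki <- 0.25 * mwi[sb] + 0.75 * spki
          }
        }
      }
      if (length(qrs)) rr_recent <- c(rr_recent, i - qrs[length(qrs)])
      qrs <- c(qrs, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  # map back to the original record: undo delay, snap to local maximum
  out <- integer(0)
  half <- round(0.075 * fs)
  for (i in qrs) {
    c0 <- min(max(i - delay, 1L), n)
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    out <- c(out, lo + which.max(record$samples[lo:hi]) - 1L)
  }
  out <- sort(unique(out))
  out[c(TRUE, diff(out) >= refr)]
}
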