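#' Time-domain HRV summary
#'
#' Computes the standard time-domain heart-rate-variability statistics from
#' an RR-interval series, plus the Poincare descriptors:
#'
#' * SDNN: population standard deviation of the RR intervals, ms.
#' * RMSSD: root mean square of successive RR differences, ms. Two
#'   denominator conventions are provided: `"paper"` divides the summed
#'   squared differences by the length `M` of the RR vector, `"standard"` by
#'   the number of differences `M - 1`. The paper convention is the default
#'   and is always strictly smaller whenever any difference is nonzero.
#' * NN50: count of successive differences exceeding 50 ms.
#' * mean heart rate: `60 / mean(rr)` bpm.
#' * SD1/SD2: Poincare dispersions, see [poincare()].
#'
#' @param rr numeric RR intervals in seconds, at least 3, all positive.
#' @param rmssd_convention `"paper"` or `"standard"` (see above).
#' @return An object of class `hrv_summary` with fields `sdnn_ms`,
#'   `rmssd_ms`, `nn50`, `mean_hr_bpm`, `sd1_ms`, `sd2_ms`,
#'   `rmssd_convention`, `n_rr`.
#' @examples
#' hrv_summary(c(0.8, 0.9, 0.8))           # RMSSD sqrt(20000/3) ~= 81.65 ms
#' hrv_summary(c(0.8, 0.9, 0.8), "standard")  # 100 ms
#' @export
hrv_summary <- function(rr, rmssd_convention = c("paper", "standard")) {
  rmssd_convention <- match.arg(rmssd_convention)
  rr <- as.numeric(rr)
  if (length(rr) < 3L) stop("hrv_summary() needs at least 3 RR intervals", call. = FALSE)
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("RR intervals must be positive and finite", call. = FALSE)
  }
  d <- diff(rr)
  m <- length(rr)
  denom <- if (rmssd_convention == "paper") m else m - 1L
  rmssd <- sqrt(sum(d^2) / denom) * 1000
  pc <- poincare(rr)
  structure(list(
    sdnn_ms = pop_sd(rr) * 1000,
    rmssd_ms = rmssd,
    nn50 = sum(abs(d) > 0.050),
    mean_hr_bpm = 60 / mean(rr),
    sd1_ms = pc$sd1_ms,
    sd2_ms = pc$sd2_ms,
    rmssd_convention = rmssd_convention,
    n_rr = m
  ), class = "hrv_summary")
}

#' @export
print.hrv_summary <- function(x, ...) {
  cat(sprintf(
    "<hrv_summary> %d RR intervals, mean HR %.1f bpm\n  SDNN %.2f ms | RMSSD %.2f ms (%s convention) | NN50 %d\n  Poincare SD1 %.2f ms, SD2 %.2f ms\n",
    x$n_rr, x$mean_hr_bpm, x$sdnn_ms, x$rmssd_ms, x$rmssd_convention,
    x$nn50, x$sd1_ms, x$sd2_ms))
  invisible(x)
}

#' Poincare descriptors of an RR series
#'
#' The Poincare plot scatters each RR interval against its successor. SD1,
#' the dispersion across the identity line, is the root mean square of the
#' successive differences divided by `sqrt(2)` (computed about zero, the
#' stationarity assumption), so `SD1 = RMSSD_standard / sqrt(2)` holds
#' exactly. SD2, the dispersion along the identity line, is the
#' mean-centred population SD of `(rr[n] + rr[n+1]) / sqrt(2)`.
#'
#' @param rr numeric RR intervals in seconds, at least 3.
#' @return list with `sd1_ms`, `sd2_ms`, and `points` — a two-column matrix
#'   (`rr_n`, `rr_next`) with `length(rr) - 1` rows.
#' @export
poincare <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 3L) stop("poincare() needs at least 3 RR intervals", call. = FALSE)
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("RR intervals must be positive and finite", call. = FALSE)
  }
  d <- diff(rr)
  s <- rr[-length(rr)] + rr[-1]
  list(
    sd1_ms = sqrt(mean(d^2) / 2) * 1000,
    sd2_ms = pop_sd(s / sqrt(2)) * 1000,
    points = cbind(rr_n = rr[-length(rr)], rr_next = rr[-1])
  )
}
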