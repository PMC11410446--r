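#' Detected QRS landmarks for a record
#'
#' Holds per-beat Q, R and S sample indices (1-based, R mandatory), QRS
#' trough-to-trough intervals in seconds, and RR intervals between successive
#' R peaks. Invariants: per beat `q < r < s` where Q/S are present; QRS
#' intervals lie in (0, 0.25) s; there is one RR interval fewer than R peaks
#' and every RR interval exceeds the 0.2 s physiological refractory period.
#'
#' @param r integer vector of R-peak sample indices, strictly increasing.
#' @param q,s integer vectors of Q and S indices (NA where not located),
#'   same length as `r`.
#' @param fs sampling rate in Hz; used to derive RR intervals when `rr` is
#'   not given.
#' @param qrs numeric vector of QRS intervals in seconds (NA allowed).
#' @param rr numeric vector of RR intervals in seconds; computed from `r`
#'   and `fs` when omitted.
#' @return An object of class `qrs_annotation`.
#' @export
qrs_annotation <- function(r, q = rep(NA_integer_, length(r)),
                           s = rep(NA_integer_, length(r)),
                           fs = NULL, qrs = rep(NA_real_, length(r)),
                           rr = NULL) {
  r <- as.integer(r)
  q <- as.integer(q)
  s <- as.integer(s)
  qrs <- as.numeric(qrs)
  if (length(q) != length(r) || length(s) != length(r) || length(qrs) != length(r)) {
    stop("q, s and qrs must have one entry per R peak", call. = FALSE)
  }
  if (length(r) && (any(r < 1L) || any(diff(r) <= 0L))) {
    stop("R indices must be positive and strictly increasing", call. = FALSE)
  }
  ok <- !is.na(q) & !is.na(s)
  if (any(ok & !(q < r & r < s))) {
    stop("each beat must satisfy Q < R < S", call. = FALSE)
  }
  if (any(!is.na(qrs) & (qrs <= 0 | qrs >= 0.25))) {
    stop("QRS intervals must lie in (0, 0.25) s", call. = FALSE)
  }
  if (is.null(rr)) {
    if (is.null(fs) && length(r) > 1L) {
      stop("either 'fs' or 'rr' must be supplied", call. = FALSE)
    }
    rr <- if (length(r) > 1L) diff(r) / fs else numeric(0)
  }
  rr <- as.numeric(rr)
  if (length(r) > 0L && length(rr) != length(r) - 1L) {
    stop("there must be one RR interval fewer than R peaks", call. = FALSE)
  }
  if (any(rr <= 0.2)) {
    stop("RR intervals must exceed the 0.2 s refractory period", call. = FALSE)
  }
  structure(list(r = r, q = q, s = s, qrs = qrs, rr = rr, fs = fs),
            class = "qrs_annotation")
}

#' @export
print.qrs_annotation <- function(x, ...) {
  cat(sprintf("<qrs_annotation> %d beats", length(x$r)))
  if (length(x$rr)) {
    cat(sprintf(", mean RR %.3f s (%.1f bpm)", mean(x$rr), 60 / mean(x$rr)))
  }
  if (any(!is.na(x$qrs))) {
    cat(sprintf(", mean QRS %.3f s", mean(x$qrs, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}
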