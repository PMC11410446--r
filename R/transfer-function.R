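#' Rational transfer functions
#'
#' A `transfer_function` describes a linear filter as a ratio of two
#' polynomials. Coefficients are stored in descending power: for an analog
#' (`domain = "s"`) function `H(s) = num(s)/den(s)` they are powers of `s`;
#' for a digital (`domain = "z"`) function they are filter taps, i.e.
#' `H(z) = sum(num[k] z^-(k-1)) / sum(den[k] z^-(k-1))`, the convention used
#' by [signal::filter()]. Digital functions carry their sampling rate.
#'
#' @param num numeric vector of numerator coefficients, descending power.
#' @param den numeric vector of denominator coefficients, descending power.
#'   The leading coefficient must be nonzero. Defaults to `1` (an FIR filter).
#' @param domain `"z"` for digital, `"s"` for analog.
#' @param fs sampling rate in Hz; required when `domain = "z"`.
#' @return An object of class `transfer_function`.
#' @examples
#' h <- transfer_function(c(3, 14), 41, domain = "s")
#' evaluate_response(h, 0)  # 14/41
#' @export
transfer_function <- function(num, den = 1, domain = c("z", "s"), fs = NULL) {
  domain <- match.arg(domain)
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (length(den) == 0L || all(den == 0)) {
    stop("denominator must be nonempty with a nonzero coefficient", call. = FALSE)
  }
  if (den[1] == 0) stop("denominator leading coefficient must be nonzero", call. = FALSE)
  if (length(num) == 0L) num <- 0
  if (!all(is.finite(num)) || !all(is.finite(den))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  if (domain == "z") {
    if (is.null(fs)) stop("digital transfer functions require 'fs'", call. = FALSE)
    stop_if_not_scalar(fs, "fs")
    if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  } else {
    fs <- NULL
  }
  structure(list(num = num, den = den, domain = domain, fs = fs),
            class = "transfer_function")
}

is_transfer_function <- function(x) inherits(x, "transfer_function")

#' @export
print.transfer_function <- function(x, ...) {
  kind <- if (x$domain == "z") sprintf("digital (fs = %g Hz)", x$fs) else "analog"
  cat(sprintf("<transfer_function> %s, numerator degree %d, denominator degree %d\n",
              kind, length(x$num) - 1L, length(x$den) - 1L))
  cat("  num:", paste(signif(x$num, 6), collapse = " "), "\n")
  cat("  den:", paste(signif(x$den, 6), collapse = " "), "\n")
  invisible(x)
}

#' Order of a transfer function
#'
#' The larger of the numerator and denominator polynomial degrees.
#'
#' @param tf a [transfer_function()].
#' @return integer order.
#' @export
filter_order <- function(tf) {
  stopifnot(is_transfer_function(tf))
  max(length(tf$num), length(tf$den)) - 1L
}

#' Stability of a transfer function
#'
#' An analog filter is stable when every denominator root has a strictly
#' negative real part; a digital filter when every pole lies strictly inside
#' the unit circle.
#'
#' @param tf a [transfer_function()].
#' @return `TRUE` or `FALSE`.
#' @export
is_stable <- function(tf) {
  stopifnot(is_transfer_function(tf))
  if (length(tf$den) == 1L) return(TRUE)  # FIR
  if (tf$domain == "z") {
    # poles: roots of den interpreted as polynomial in z
    r <- polyroot(rev(tf$den))
    all(Mod(r) < 1)
  } else {
    r <- polyroot(rev(tf$den))
    all(Re(r) < 0)
  }
}

#' Evaluate the frequency response of a transfer function
#'
#' Analog functions are evaluated at `s = 2i * pi * f`; digital functions at
#' `z = exp(2i * pi * f / fs)`. A frequency at which the denominator vanishes
#' (within machine tolerance) yields `NA` with a warning rather than an
#' unbounded value.
#'
#' @param tf a [transfer_function()].
#' @param frequencies numeric vector of frequencies in Hz. Digital functions
#'   require all frequencies below the Nyquist rate; analog functions require
#'   nonnegative frequencies.
#' @return complex vector of gains, one per frequency.
#' @export
evaluate_response <- function(tf, frequencies) {
  stopifnot(is_transfer_function(tf))
  f <- as.numeric(frequencies)
  if (length(f) == 0L) stop("'frequencies' must be nonempty", call. = FALSE)
  if (tf$domain == "z") {
    if (any(f >= tf$fs / 2)) {
      stop("frequencies must be below the Nyquist rate fs/2", call. = FALSE)
    }
    x <- exp(-2i * pi * f / tf$fs)  # z^-1; taps are ascending powers of z^-1
    num <- poly_eval(rev(tf$num), x)
    den <- poly_eval(rev(tf$den), x)
  } else {
    if (any(f < 0)) stop("analog frequencies must be nonnegative", call. = FALSE)
    s <- 2i * pi * f
    num <- poly_eval(tf$num, s)
    den <- poly_eval(tf$den, s)
  }
  bad <- Mod(den) < .Machine$double.eps * (1 + max(abs(tf$den)))
  if (any(bad)) {
    warning(sprintf("denominator vanishes at %d frequenc%s; returning NA there",
                    sum(bad), if (sum(bad) == 1L) "y" else "ies"))
  }
  out <- num / den
  out[bad] <- NA_complex_
  out
}

#' Cascade (series connection) of two transfer functions
#'
#' The cascade multiplies responses: numerators and denominators are
#' polynomial products, so degrees add.
#'
#' @param a,b [transfer_function()] objects in the same domain (and, for
#'   digital functions, the same sampling rate).
#' @return a [transfer_function()].
#' @export
cascade <- function(a, b) {
  stopifnot(is_transfer_function(a), is_transfer_function(b))
  if (a$domain != b$domain) stop("cannot cascade filters from different domains", call. = FALSE)
  if (a$domain == "z" && !isTRUE(all.equal(a$fs, b$fs))) {
    stop("cannot cascade digital filters with different sampling rates", call. = FALSE)
  }
  transfer_function(poly_mult(a$num, b$num), poly_mult(a$den, b$den),
                    domain = a$domain, fs = a$fs)
}

#' Discretize an analog transfer function by the bilinear transform
#'
#' Substitutes `s = 2 * fs * (z - 1) / (z + 1)` into both polynomials,
#' yielding a digital transfer function at sampling rate `fs`. No frequency
#' pre-warping is applied.
#'
#' @param tf an analog [transfer_function()].
#' @param fs target sampling rate in Hz.
#' @return a digital [transfer_function()].
#' @export
bilinear_tf <- function(tf, fs) {
  stopifnot(is_transfer_function(tf))
  if (tf$domain != "s") stop("bilinear_tf() expects an analog transfer function", call. = FALSE)
  stop_if_not_scalar(fs, "fs")
  n_deg <- max(length(tf$num), length(tf$den)) - 1L
  k <- 2 * fs
  sub_poly <- function(coef) {
    # pad to common degree so both polynomials share the (z+1)^n_deg factor
    coef <- c(rep(0, n_deg + 1L - length(coef)), coef)
    out <- rep(0, n_deg + 1L)
    for (j in 0:n_deg) {
      # coefficient of s^(n_deg - j) times (k (z-1))^(n_deg-j) (z+1)^j
      p <- 1
      e <- n_deg - j
      if (e > 0) for (q in seq_len(e)) p <- poly_mult(p, k * c(1, -1))
      if (j > 0) for (q in seq_len(j)) p <- poly_mult(p, c(1, 1))
      out <- out + coef[j + 1L] * p
    }
    out
  }
  num <- sub_poly(tf$num)
  den <- sub_poly(tf$den)
  # strip leading zeros of the denominator, normalize leading coefficient
  lead <- which(abs(den) > .Machine$double.eps * max(abs(den)))[1]
  den <- den[lead:length(den)]
  transfer_function(num / den[1], den / den[1], domain = "z", fs = fs)
}

#' Write and read transfer-function coefficients as CSV
#'
#' The file holds one coefficient per line in two sections introduced by
#' `numerator` and `denominator` marker lines; a leading comment line records
#' the domain and sampling rate, so the round trip is lossless.
#'
#' @param tf a [transfer_function()].
#' @param path file path.
#' @return `read_tf_csv()` returns a [transfer_function()];
#'   `write_tf_csv()` returns `path` invisibly.
#' @export
write_tf_csv <- function(tf, path) {
  stopifnot(is_transfer_function(tf))
  hdr <- if (tf$domain == "z") sprintf("# domain=z fs=%.10g", tf$fs) else "# domain=s"
  lines <- c(hdr, "numerator", sprintf("%.17g", tf$num),
             "denominator", sprintf("%.17g", tf$den))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tf_csv
#' @export
read_tf_csv <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  domain <- "z"
  fs <- NULL
  if (startsWith(lines[1], "#")) {
    domain <- if (grepl("domain=s", lines[1], fixed = TRUE)) "s" else "z"
    m <- regmatches(lines[1], regexpr("fs=[0-9.eE+-]+", lines[1]))
    if (length(m)) fs <- as.numeric(sub("fs=", "", m))
    lines <- lines[-1]
  }
  i_num <- which(lines == "numerator")
  i_den <- which(lines == "denominator")
  if (length(i_num) != 1L || length(i_den) != 1L || i_den <= i_num) {
    stop("malformed coefficient file: expected 'numerator' then 'denominator' sections",
         call. = FALSE)
  }
  num <- as.numeric(lines[(i_num + 1L):(i_den - 1L)])
  den <- as.numeric(lines[(i_den + 1L):length(lines)])
  transfer_function(num, den, domain = domain, fs = fs)
}
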