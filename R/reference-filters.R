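#' Example transfer functions used as evaluation fixtures
#'
#' Fixed rational transfer functions of the kind each design stage produces,
#' kept for response-evaluation tests and demonstrations. All are analog
#' (s-domain) descriptions; discretize with [bilinear_tf()] before applying
#' them to sampled data.
#'
#' * `example_bandpass_tf()`: a 4th-order band-pass stage.
#' * `example_iir16_tf()`: a 16th-order IIR stop-band stage. Note this
#'   example is an evaluation fixture only: its denominator, as tabulated,
#'   is not stable, so it is never used to filter data (the package designs
#'   its own stable cascade with [design_iir_cascade()]).
#' * `example_reduced_tf()`: `(3 s + 14) / 41`, the shape of an order-reduced
#'   all-nonnegative-coefficient result.
#' * `example_pt_lowpass_tf()`: the integer-coefficient low-pass used by the
#'   classic Pan-Tompkins preprocessing chain, in its tabulated rational
#'   form (also unstable as written; a parsing/evaluation fixture only).
#'
#' @return an analog [transfer_function()].
#' @name example_filters
NULL

#' @rdname example_filters
#' @export
example_bandpass_tf <- function() {
  transfer_function(c(0.2066, 0, -0.4131, 0, 0.2066),
                    c(1, 0.5488, 0.4535, 0.1763, 0.1958), domain = "s")
}

#' @rdname example_filters
#' @export
example_iir16_tf <- function() {
  num <- c(0.3201, 4.517, 30.45, 130, 393.2, 892.9, 1574, 2196, 2452,
           2196, 1574, 892.9, 393.2, 130, 30.45, 4.517, 0.3201)
  den <- c(1, 12.12, 70.25, 258.1, 672.2, 1316, 2004, 2419, 2340,
           1819, 113, 559.4, 214.8, 62, 12.7, 1.649, 0.102)
  transfer_function(num, den, domain = "s")
}

#' @rdname example_filters
#' @export
example_reduced_tf <- function() {
  transfer_function(c(3, 14), 41, domain = "s")
}

#' @rdname example_filters
#' @export
example_pt_lowpass_tf <- function() {
  num <- numeric(13)
  num[c(1, 7, 13)] <- c(0.03125, -0.0625, 0.03125)
  transfer_function(num, c(1, -2, 1), domain = "s")
}

#' Path to the example 61-tap FIR coefficient file
#'
#' A tabulated 61-coefficient (order 60) linear-phase FIR design shipped as
#' a plain-text coefficient file in the format written by [write_tf_csv()];
#' used to exercise the coefficient parser and the linear-phase symmetry
#' check.
#'
#' @return file path.
#' @export
example_fir60_path <- function() {
  system.file("extdata", "fir60_example_taps.csv", package = "ecgflow",
              mustWork = TRUE)
}
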