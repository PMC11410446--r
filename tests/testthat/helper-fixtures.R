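# shared fixtures and independent oracles

# noise-free simulation settings
quiet_config <- function(duration_s = 30, heart_rate_bpm = 60, rr_jitter_sd = 0,
                         seed = 1L, ...) {
  simulation_config(fs = 360, duration_s = duration_s,
                    heart_rate_bpm = heart_rate_bpm, rr_jitter_sd = rr_jitter_sd,
                    baseline_amp = 0, powerline_amp = 0, noise_sd = 0,
                    seed = seed, ...)
}

# count detected peaks matching ground truth within a window (seconds)
match_count <- function(detected, truth_idx, fs, window = 0.05) {
  w <- round(window * fs)
  sum(vapply(truth_idx, function(tr) any(abs(detected - tr) <= w), logical(1)))
}

# independent oracle for the Hilbert transform: principal-value convolution
# with the 1/(pi t) kernel, discretized at odd-lag midpoints (step 2*dt
# centred between samples, which respects the kernel's odd symmetry)
hilbert_pv_oracle <- function(x, at, max_lag = 199) {
  n <- length(x)
  lags <- seq(1, max_lag, by = 2)
  vapply(at, function(i) {
    s <- 0
    for (k in lags) {
      if (i - k >= 1) s <- s + x[i - k] / k
      if (i + k <= n) s <- s - x[i + k] / k
    }
    2 * s / pi
  }, numeric(1))
}

# pack 12-bit two's-complement sample pairs into WFDB format-212 bytes
pack_wfdb_212 <- function(samples) {
  if (length(samples) %% 2 != 0) samples <- c(samples, 0L)
  u <- ifelse(samples < 0, samples + 4096L, samples)
  s1 <- u[seq(1, length(u), 2)]
  s2 <- u[seq(2, length(u), 2)]
  as.raw(rbind(bitwAnd(s1, 0xFFL),
               bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L)),
               bitwAnd(s2, 0xFFL)))
}

# brute-force maximum response deviation by an explicit loop (oracle)
deviation_loop_oracle <- function(a, b, grid) {
  worst <- 0
  for (f in grid) {
    d <- abs(Mod(evaluate_response(a, f)) - Mod(evaluate_response(b, f)))
    if (d > worst) worst <- d
  }
  worst
}
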