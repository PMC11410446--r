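test_that("the envelope recovers a sinusoid's amplitude and dominates the signal", {
  t <- (0:3599) / 360
  for (A in c(0.5, 2)) {
    x <- A * cos(2 * pi * 5 * t)
    env <- hilbert_envelope(x)
    mid <- 361:3240  # middle 80%
    expect_lt(max(abs(env[mid] - A)) / A, 0.01)
    expect_true(all(env >= abs(x) - 1e-12))
  }
  set.seed(7)
  for (k in 1:5) {
    x <- rnorm(512)
    expect_true(all(hilbert_envelope(x) >= abs(x) - 1e-12))
  }
  # constant signal: envelope equals |constant|
  expect_equal(hilbert_envelope(rep(-2, 64)), rep(2, 64))
})

test_that("the analytic signal's imaginary part matches the principal-value integral", {
  t <- (0:1023) / 256
  x <- cos(2 * pi * 8 * t)
  # package path: frequency-domain analytic signal
  X <- fft(x)
  h <- numeric(1024); h[c(1, 513)] <- 1; h[2:512] <- 2
  imag_fft <- Im(fft(X * h, inverse = TRUE) / 1024)
  at <- 200:300
  # oracle: discretized principal-value convolution with 1/(pi t)
  imag_pv <- hilbert_pv_oracle(x, at)
  expect_lt(max(abs(imag_pv - sin(2 * pi * 8 * t[at]))), 0.02)
  expect_lt(max(abs(imag_fft[at] - sin(2 * pi * 8 * t[at]))), 0.02)
})

test_that("R-peak detection recovers clean and noisy synthetic beats", {
  expect_length(detect_r_peaks(rep(0, 1000), 360), 0)

  sim <- generate_ecg(quiet_config(duration_s = 30, heart_rate_bpm = 60))
  env <- hilbert_envelope(sim$record)
  r <- detect_r_peaks(env, 360)
  expect_length(r, 30)
  expect_lte(max(abs(r - sim$truth$r)) / 360, 0.010)
  expect_true(all(diff(r) >= round(0.2 * 360)))

  # 100 beats at 10 dB SNR through the preprocessing front end
  cfg <- quiet_config(duration_s = 81, heart_rate_bpm = 75, rr_jitter_sd = 0.02,
                      seed = 7L)
  clean <- generate_ecg(cfg)
  snr_sd <- sqrt(mean(clean$record$samples^2) / 10)
  noisy <- clean$record
  set.seed(99)
  noisy$samples <- noisy$samples + rnorm(length(noisy$samples), 0, snr_sd)
  prep <- suppressMessages(preprocess_record(noisy))
  ana <- analyze_record(prep)
  truth <- clean$truth$r
  expect_gte(length(truth), 100)
  matched <- match_count(ana$annotation$r, truth, 360, window = 0.05)
  expect_gte(matched / length(truth), 0.99)
})

test_that("Q and S localization finds the template troughs and the standard width", {
  sim <- generate_ecg(quiet_config(duration_s = 30, heart_rate_bpm = 60))
  ann <- locate_qs(sim$record, sim$truth$r)
  expect_true(all(ann$q < ann$r & ann$r < ann$s))
  expect_lt(abs(mean(ann$qrs) - 0.099), 0.02)

  # oracle: argmin of the densely sampled clean template on each side
  tpl <- beat_template()
  toff <- seq(-0.12, 0.12, by = 1e-4)
  wave <- tpl$amplitudes[["r"]] * exp(-toff^2 / (2 * tpl$widths[["r"]]^2))
  for (w in c("p", "q", "s", "t")) {
    wave <- wave + tpl$amplitudes[[w]] *
      exp(-(toff - tpl$centers[[w]])^2 / (2 * tpl$widths[[w]]^2))
  }
  q_true <- toff[toff < 0][which.min(wave[toff < 0])]
  s_true <- toff[toff > 0][which.min(wave[toff > 0])]
  expect_lte(max(abs((ann$q - ann$r) / 360 - q_true)), 1.5 / 360)
  expect_lte(max(abs((ann$s - ann$r) / 360 - s_true)), 1.5 / 360)

  # beats at the record edge are dropped with a warning
  expect_warning(locate_qs(sim$record, c(3L, sim$truth$r)), "dropped")
})

test_that("rr_intervals does plain interval arithmetic", {
  expect_equal(rr_intervals(c(1, 361, 721), 360), c(1, 1))
  expect_length(rr_intervals(100, 360), 0)
  expect_length(rr_intervals(integer(0), 360), 0)
  expect_error(rr_intervals(c(10, 5), 360), "increasing")
})

test_that("Pan-Tompkins detects clean beats and agrees with the Hilbert detector", {
  expect_error(pan_tompkins(ecg_record(rnorm(360), fs = 360)), "2 s")

  sim <- generate_ecg(quiet_config(duration_s = 60, heart_rate_bpm = 80, seed = 2L))
  pt <- pan_tompkins(sim$record)
  truth <- sim$truth$r
  expect_gte(match_count(pt, truth, 360, 0.05), length(truth) - 1L)

  env <- hilbert_envelope(sim$record)
  hil <- detect_r_peaks(env, 360)
  expect_lte(abs(length(pt) - length(hil)), 1)
})
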