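test_that("Butterworth band filters meet their band-edge contracts", {
  bp <- design_butterworth("pass", 5, 15, order = 2, fs = 360)
  expect_true(is_stable(bp))
  gains <- Mod(evaluate_response(bp, c(5, sqrt(5 * 15), 15)))
  expect_gte(gains[2], 0.89)
  expect_equal(gains[c(1, 3)], rep(1 / sqrt(2), 2), tolerance = 0.01)

  bs <- design_butterworth("stop", 49, 51, order = 2, fs = 360)
  expect_true(is_stable(bs))
  expect_lte(Mod(evaluate_response(bs, 50)), 0.1)

  expect_error(design_butterworth("pass", 200, 250, 2, fs = 360), "Nyquist")
  expect_error(design_butterworth("pass", 5, 15, 0, fs = 360), "order")
})

test_that("FIR designs are linear phase with the stated tap count", {
  hp <- design_fir("highpass", 0.5, order = 60, fs = 360)
  expect_length(hp$num, 61)
  expect_identical(hp$den, 1)
  expect_lte(abs(sum(hp$num)), 1e-3)                   # DC nulled
  expect_equal(hp$num, rev(hp$num), tolerance = 1e-9)  # symmetric

  bs <- design_fir("bandstop", c(45, 55), order = 100, fs = 360)
  expect_length(bs$num, 101)
  expect_equal(bs$num, rev(bs$num), tolerance = 1e-9)
  expect_lte(Mod(evaluate_response(bs, 50)), 0.1)
  expect_gte(Mod(evaluate_response(bs, 10)), 0.9)

  expect_error(design_fir("bandstop", c(45, 200), 100, fs = 360), "cutoff")
})

test_that("the shipped 61-tap example coefficient file parses and is symmetric", {
  tf60 <- read_tf_csv(example_fir60_path())
  expect_length(tf60$num, 61)
  expect_identical(tf60$num[1], tf60$num[61])
  expect_identical(tf60$num[1], 4.168e-19 * -1)
  expect_identical(tf60$num[2], 0.0004528)
  expect_equal(tf60$num, rev(tf60$num))
})

test_that("cascade multiplies responses and adds degrees", {
  bp <- design_butterworth("pass", 5, 15, 2, fs = 360)
  bs2 <- design_butterworth("stop", 40, 60, 2, fs = 360)
  unity <- transfer_function(1, 1, domain = "z", fs = 360)
  grid <- seq(1, 170, length.out = 50)

  expect_equal(evaluate_response(cascade(unity, bp), grid),
               evaluate_response(bp, grid))
  casc <- cascade(bp, bs2)
  expect_equal(filter_order(casc), filter_order(bp) + filter_order(bs2))
  expect_lt(max(abs(Mod(evaluate_response(casc, grid)) -
                      Mod(evaluate_response(bp, grid)) *
                      Mod(evaluate_response(bs2, grid)))), 1e-9)
  # associativity up to round-off
  hp <- design_fir("highpass", 0.5, 60, fs = 360)
  left <- cascade(cascade(bp, bs2), hp)
  right <- cascade(bp, cascade(bs2, hp))
  expect_lt(max(abs(Mod(evaluate_response(left, grid)) -
                      Mod(evaluate_response(right, grid)))), 1e-9)
  expect_error(cascade(bp, example_bandpass_tf()), "domain")

  # the narrow degree-16 cascade: near-unit-circle poles limit polynomial
  # round-off to ~1e-6 in the product identity
  casc16 <- design_iir_cascade(fs = 360)
  bs6 <- design_butterworth("stop", 49, 51, 6, fs = 360)
  expect_lt(max(abs(Mod(evaluate_response(casc16, grid)) -
                      Mod(evaluate_response(bp, grid)) *
                      Mod(evaluate_response(bs6, grid)))), 1e-5)

  # the analog example stages: degree-4 band-pass times degree-16 stop band
  analog <- cascade(example_bandpass_tf(), example_iir16_tf())
  expect_equal(length(analog$num) - 1L, 20L)
})

test_that("analog example responses match direct arithmetic on their coefficients", {
  expect_equal(Mod(evaluate_response(example_reduced_tf(), 0)), 14 / 41)
  expect_equal(Mod(evaluate_response(example_bandpass_tf(), 0)), 0.2066 / 0.1958)
  expect_equal(Mod(evaluate_response(transfer_function(1, 1, domain = "z", fs = 360),
                                     c(0, 10, 100))), rep(1, 3))
})

test_that("apply_filter honours identity, annihilator, and frequency selectivity", {
  sim <- generate_ecg(quiet_config(duration_s = 10))
  unity <- transfer_function(1, 1, domain = "z", fs = 360)
  expect_identical(apply_filter(unity, sim$record)$samples, sim$record$samples)
  zero <- transfer_function(0, 1, domain = "z", fs = 360)
  expect_true(all(apply_filter(zero, sim$record)$samples == 0))

  lp <- design_lowpass(40, order = 4, fs = 360)
  t <- (0:7199) / 360
  amp_of <- function(f) {
    y <- apply_filter(lp, ecg_record(sin(2 * pi * f * t), fs = 360))$samples
    # FFT amplitude of the steady-state segment at the drive frequency
    seg <- y[3601:7200]
    2 * Mod(fft(seg)[round(f * length(seg) / 360) + 1]) / length(seg)
  }
  expect_equal(amp_of(1), 1, tolerance = 0.02)
  expect_lt(amp_of(100), 10^(-20 / 20))

  wrong_fs <- design_lowpass(40, 4, fs = 500)
  expect_error(apply_filter(wrong_fs, sim$record), "fs")
  unstable <- transfer_function(1, c(1, -2), domain = "z", fs = 360)
  expect_error(apply_filter(unstable, sim$record), "unstable")
  expect_error(apply_filter(example_bandpass_tf(), sim$record), "bilinear")
})

test_that("zero-phase filtering cancels the group delay", {
  sim <- generate_ecg(quiet_config(duration_s = 20, heart_rate_bpm = 72, seed = 4L))
  bp <- design_butterworth("pass", 5, 15, 2, fs = 360)
  fwd <- apply_filter(bp, sim$record)$samples
  zp <- apply_filter(bp, sim$record, zero_phase = TRUE)$samples
  expect_length(zp, length(sim$record$samples))
  r <- sim$truth$r[5]
  win <- (r - 36):(r + 36)
  peak_zp <- win[which.max(zp[win])]
  peak_fwd <- win[which.max(fwd[win])]
  expect_lte(abs(peak_zp - r), 3)        # aligned
  expect_gte(peak_fwd, peak_zp)          # the forward run never leads
})

test_that("every designed filter in the default chain is stable", {
  designs <- list(
    design_butterworth("pass", 5, 15, 2, fs = 360),
    design_butterworth("stop", 49, 51, 6, fs = 360),
    design_lowpass(150, 4, fs = 360),
    design_fir("highpass", 0.5, 60, fs = 360),
    design_fir("bandstop", c(45, 55), 100, fs = 360),
    design_iir_cascade(fs = 360)
  )
  for (d in designs) expect_true(is_stable(d))
})

test_that("bilinear discretization preserves the low-frequency response", {
  rc <- transfer_function(1, c(1 / (2 * pi * 10), 1), domain = "s")  # 10 Hz pole
  dz <- bilinear_tf(rc, 360)
  expect_true(is_stable(dz))
  f <- c(0.5, 2, 5, 10)
  expect_equal(Mod(evaluate_response(dz, f)),
               Mod(evaluate_response(rc, f)), tolerance = 0.02)
})

test_that("transfer-function coefficient CSVs round trip", {
  tf <- design_iir_cascade(fs = 360)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tf_csv(tf, path)
  back <- read_tf_csv(path)
  expect_equal(back$num, tf$num)
  expect_equal(back$den, tf$den)
  expect_identical(back$fs, tf$fs)
  expect_identical(back$domain, "z")
})
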