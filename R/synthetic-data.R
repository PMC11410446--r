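#' Beat morphology template
#'
#' A synthetic heartbeat is a sum of five Gaussian bumps (P, Q, R, S, T),
#' each with an amplitude in mV, a center offset from the R peak in seconds,
#' and a Gaussian width (standard deviation) in seconds. The R wave is
#' centered at offset 0 by definition.
#'
#' The default widths put the clean composite QRS trough-to-trough width at
#' 0.099 s, the standard QRS duration the classification rules take as the
#' regular-rhythm reference.
#'
#' @param amplitudes named numeric vector `c(p=, q=, r=, s=, t=)` in mV.
#' @param centers named numeric vector of offsets from R in seconds (the `r`
#'   entry must be 0; `q` negative, `s` positive).
#' @param widths named numeric vector of Gaussian SDs in seconds, all
#'   positive.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(amplitudes = c(p = 0.15, q = -0.15, r = 1.0, s = -0.2, t = 0.3),
                          centers = c(p = -0.2, q = -0.035, r = 0, s = 0.035, t = 0.3),
                          widths = c(p = 0.04, q = 0.023, r = 0.018, s = 0.027, t = 0.07)) {
  waves <- c("p", "q", "r", "s", "t")
  for (v in list(amplitudes, centers, widths)) {
    if (!all(waves %in% names(v))) stop("template vectors need entries p,q,r,s,t", call. = FALSE)
  }
  amplitudes <- amplitudes[waves]; centers <- centers[waves]; widths <- widths[waves]
  if (!(centers["q"] < 0 && centers["s"] > 0 && centers["r"] == 0)) {
    stop("template requires Q offset < 0 = R offset < S offset", call. = FALSE)
  }
  if (amplitudes["r"] <= 0) stop("R amplitude must be positive", call. = FALSE)
  if (any(widths <= 0)) stop("all wave widths must be positive", call. = FALSE)
  structure(list(amplitudes = amplitudes, centers = centers, widths = widths),
            class = "beat_template")
}

# evaluate the clean template at offsets (s) from the R peak
template_wave <- function(template, t_offset, width_scale = 1) {
  out <- numeric(length(t_offset))
  for (w in c("p", "q", "r", "s", "t")) {
    sd_w <- template$widths[[w]] * width_scale
    out <- out + template$amplitudes[[w]] *
      exp(-(t_offset - template$centers[[w]])^2 / (2 * sd_w^2))
  }
  out
}

#' Simulation settings for synthetic ECG
#'
#' Describes one simulated recording: duration and sampling rate, mean heart
#' rate, beat-to-beat RR jitter, and the three artifact sources the
#' preprocessing stages target — low-frequency baseline wander, mains
#' (power-line) interference at 50 or 60 Hz, and additive white noise. A
#' fraction of beats may be generated with widened QRS complexes (width
#' multiplier applied to the Q/R/S Gaussians), which is how irregular-rhythm
#' records are emulated.
#'
#' @param fs sampling rate, Hz (default 360, the MIT-BIH rate).
#' @param duration_s record length in seconds.
#' @param heart_rate_bpm mean heart rate in beats per minute.
#' @param rr_jitter_sd SD of beat-to-beat RR deviations, seconds.
#' @param baseline_amp,baseline_freq baseline-wander amplitude (mV) and
#'   frequency (Hz).
#' @param powerline_amp,powerline_freq mains interference amplitude (mV) and
#'   frequency (50 or 60 Hz).
#' @param noise_sd white-noise SD, mV.
#' @param wide_beat_fraction fraction of beats drawn with widened QRS.
#' @param wide_beat_factor QRS width multiplier for those beats.
#' @param seed integer random seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(fs = 360, duration_s = 60, heart_rate_bpm = 75,
                              rr_jitter_sd = 0.02,
                              baseline_amp = 0.1, baseline_freq = 0.3,
                              powerline_amp = 0.05, powerline_freq = 50,
                              noise_sd = 0.01,
                              wide_beat_fraction = 0, wide_beat_factor = 1.8,
                              seed = 1L) {
  for (nm in c("fs", "duration_s", "heart_rate_bpm", "rr_jitter_sd",
               "baseline_amp", "baseline_freq", "powerline_amp",
               "powerline_freq", "noise_sd")) {
    stop_if_not_scalar(get(nm), nm)
  }
  if (fs <= 2 * powerline_freq) {
    stop("sampling rate must exceed twice the power-line frequency", call. = FALSE)
  }
  mean_rr <- 60 / heart_rate_bpm
  if (duration_s <= 2 * mean_rr) {
    stop("duration must exceed two mean RR intervals", call. = FALSE)
  }
  if (min(baseline_amp, powerline_amp, noise_sd, rr_jitter_sd) < 0) {
    stop("amplitudes and jitter SD must be nonnegative", call. = FALSE)
  }
  if (wide_beat_fraction < 0 || wide_beat_fraction > 1) {
    stop("'wide_beat_fraction' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(fs = fs, duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
                 rr_jitter_sd = rr_jitter_sd, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq, powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq, noise_sd = noise_sd,
                 wide_beat_fraction = wide_beat_fraction,
                 wide_beat_factor = wide_beat_factor, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic ECG record with ground truth
#'
#' Places beats at jittered RR intervals, renders each as the template's
#' Gaussian-sum morphology, then adds baseline wander (sinusoid at a random
#' phase), power-line interference and white noise per the configuration.
#' The same seed always reproduces the identical record.
#'
#' @param config a [simulation_config()].
#' @param template a [beat_template()].
#' @param label ground-truth rhythm label attached to the record.
#' @return A list with elements `record` (an [ecg_record()]) and `truth`
#'   (class `ecg_ground_truth`: 1-based R-peak indices `r`, true RR sequence
#'   `rr` in seconds, `label`, and per-beat QRS `width_scale`).
#' @examples
#' sim <- generate_ecg(simulation_config(duration_s = 10, heart_rate_bpm = 60,
#'                                       rr_jitter_sd = 0, baseline_amp = 0,
#'                                       powerline_amp = 0, noise_sd = 0))
#' length(sim$truth$r)  # 10 beats
#' @export
generate_ecg <- function(config, template = beat_template(),
                         label = c("regular", "irregular")) {
  stopifnot(inherits(config, "simulation_config"), inherits(template, "beat_template"))
  label <- match.arg(label)
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  mean_rr <- 60 / config$heart_rate_bpm
  # beat times: first R at half a mean RR, then jittered intervals
  t_beats <- numeric(0)
  rr_true <- numeric(0)
  t_cur <- mean_rr / 2
  margin <- min(0.35, mean_rr / 2)  # keep the QRS clear of the record edge
  while (t_cur < config$duration_s - margin) {
    t_beats <- c(t_beats, t_cur)
    rr_k <- mean_rr + rnorm(1, 0, config$rr_jitter_sd)
    rr_k <- max(rr_k, 0.3)  # physiological floor
    rr_true <- c(rr_true, rr_k)
    t_cur <- t_cur + rr_k
  }
  rr_true <- rr_true[-length(rr_true)]  # intervals between emitted beats
  nb <- length(t_beats)
  if (nb < 2L) stop("configuration yields fewer than 2 beats", call. = FALSE)
  width_scale <- rep(1, nb)
  if (config$wide_beat_fraction > 0) {
    wide <- runif(nb) < config$wide_beat_fraction
    width_scale[wide] <- config$wide_beat_factor
  }
  tt <- (0:(n - 1)) / fs
  clean <- numeric(n)
  half <- 0.5  # support of one rendered beat, seconds each side
  for (k in seq_len(nb)) {
    i0 <- max(1L, floor((t_beats[k] - half) * fs) + 1L)
    i1 <- min(n, ceiling((t_beats[k] + half) * fs) + 1L)
    idx <- i0:i1
    # QRS Gaussians widen for wide beats; P/T keep their width
    tplt <- template
    tplt$widths[c("q", "r", "s")] <- template$widths[c("q", "r", "s")] * width_scale[k]
    clean[idx] <- clean[idx] + template_wave(tplt, tt[idx] - t_beats[k])
  }
  r_idx <- round(t_beats * fs) + 1L
  x <- clean
  if (config$baseline_amp > 0) {
    x <- x + config$baseline_amp *
      sin(2 * pi * config$baseline_freq * tt + runif(1, 0, 2 * pi))
  }
  if (config$powerline_amp > 0) {
    x <- x + config$powerline_amp *
      sin(2 * pi * config$powerline_freq * tt + runif(1, 0, 2 * pi))
  }
  if (config$noise_sd > 0) x <- x + rnorm(n, 0, config$noise_sd)
  truth <- structure(list(r = r_idx, rr = rr_true, label = label,
                          width_scale = width_scale),
                     class = "ecg_ground_truth")
  list(record = ecg_record(x, fs = fs, id = sprintf("sim-%d", config$seed)),
       truth = truth)
}

#' Generate a labeled cohort of synthetic records
#'
#' Regular records use the base configuration; irregular records are drawn
#' with materially larger RR jitter (6x the base jitter, at least 0.1 s) and
#' a share of widened-QRS beats, the two ways rhythm irregularity expresses
#' itself in the features the classifiers use. Record seeds are derived from
#' the base seed, so the whole cohort is reproducible.
#'
#' @param n_regular,n_irregular number of records per class (total >= 1).
#' @param base_config a [simulation_config()] used for the regular class.
#' @param template a [beat_template()].
#' @return A list of `generate_ecg()` results (elements `record`, `truth`).
#' @export
generate_cohort <- function(n_regular, n_irregular,
                            base_config = simulation_config(),
                            template = beat_template()) {
  n_regular <- as.integer(n_regular)
  n_irregular <- as.integer(n_irregular)
  if (n_regular < 0L || n_irregular < 0L || n_regular + n_irregular < 1L) {
    stop("the cohort must contain at least one record", call. = FALSE)
  }
  irr_config <- base_config
  irr_config$rr_jitter_sd <- max(6 * base_config$rr_jitter_sd, 0.1)
  irr_config$wide_beat_fraction <- max(base_config$wide_beat_fraction, 0.3)
  out <- vector("list", n_regular + n_irregular)
  for (i in seq_len(n_regular)) {
    cfg <- base_config
    cfg$seed <- base_config$seed + i - 1L
    out[[i]] <- generate_ecg(cfg, template, label = "regular")
  }
  for (j in seq_len(n_irregular)) {
    cfg <- irr_config
    cfg$seed <- base_config$seed + n_regular + j - 1L
    out[[n_regular + j]] <- generate_ecg(cfg, template, label = "irregular")
  }
  out
}
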