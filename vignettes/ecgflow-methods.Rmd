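---
title: "ECG filtering, QRS detection and rhythm classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG filtering, QRS detection and rhythm classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgflow)
```

ecgflow implements a complete single-lead ECG analysis chain: artifact
filtering, minimax reduction of a high-order IIR filter to a low-order
all-nonnegative-coefficient one, Hilbert-envelope QRS detection,
time-domain and Poincaré heart-rate-variability (HRV) summaries, and three
regular/irregular rhythm classification rules with confusion-count
evaluation. This vignette explains the models and the design decisions; the
README shows a worked end-to-end example.

## The signal model and the synthetic generator

Every stage is testable without clinical data because the package ships its
own generator, `generate_ecg()`. A heartbeat is modelled as a sum of five
Gaussian bumps — P, Q, R, S, T — each with an amplitude (mV), a center
offset from the R peak (s), and a width (s). This is deliberately the
simplest morphology with analytically known landmark positions: the
ground-truth R index is exact by construction, and the Q/S trough positions
of the clean composite can be computed densely and used as an oracle for
the localizer.

The default template (R = 1 mV; Q = −0.15 mV at −0.035 s; S = −0.2 mV at
+0.035 s; widths 0.018/0.023/0.027 s for R/Q/S) was chosen once so that the
trough-to-trough width of the clean composite QRS is 0.0989 s, matching the
0.099 s standard QRS duration that the classification rules use as the
regular-rhythm reference. Note the composite troughs sit outside the Q/S
Gaussian centers because the R bump's flanks shift them outward — the
oracle in the tests therefore minimizes the full composite, not the
individual Gaussians.

Beats are placed at jittered intervals: RR$_k$ = 60/HR + $\varepsilon_k$,
$\varepsilon_k \sim N(0, \sigma_{RR}^2)$, floored at 0.3 s. Three artifact
sources are added per the configuration: a baseline-wander sinusoid
(default 0.1 mV at 0.3 Hz), mains interference (0.05 mV at 50 Hz), and
white noise (0.01 mV SD) — levels a scientist would call a mildly noisy
but usable clinical trace; no published noise floors exist for the study
conditions, so these are the package's own defaults. Irregular-rhythm
records in `generate_cohort()` get 6× the RR jitter (at least 0.1 s SD) and
a 30% share of widened-QRS beats (Q/R/S widths × 1.8): the two mechanisms
by which irregularity expresses itself in the features the classifiers
consume (SDNN/RMSSD and mean QRS width). Everything is seed-deterministic.

What the generator does *not* emulate: pathology-specific morphologies
(atrial fibrillation f-waves, PVC shapes), electrode motion artifacts,
non-stationary noise, multi-lead geometry. Passing tests on this generator
demonstrate parameter recovery and algorithmic correctness under the stated
conditions — not clinical performance on arrhythmia databases, which users
can assess by pointing the same pipeline at WFDB records.

## Filtering front end

The preprocessing chain in `preprocess_record()` is: baseline-wander
removal → optional 150 Hz low-pass (only when fs > 300 Hz, else the corner
would sit above Nyquist and the stage is skipped with a message) → a
two-stage Butterworth IIR cascade (band-pass 5–15 Hz of order 2, the
classic QRS-emphasis band, times band-stop mains ± 1 Hz of order 6) → the
minimax-reduced low-order smoother derived from that cascade → a
100-coefficient FIR band-stop at mains ± 5 Hz. Filtering is forward-only by
default (`zero_phase = TRUE` is available); linear-phase FIR stages are
delay-compensated by exactly order/2 samples.

Two numerical decisions deserve comment.

**The order-60 baseline high-pass.** At ECG sampling rates an order-60 FIR
simply cannot realize a 0.5 Hz cutoff: a 61-tap filter at 360 Hz resolves
about 6 Hz. A conventional windowed-sinc DC-blocker of this length is an
identity minus a 0.17 s smoother, and that smoother tracks the QRS complex
itself — measured on the clean template it clips the R amplitude by ~35%.
`design_fir("highpass", ...)` therefore switches, whenever the requested
cutoff is below the length-limited resolution (cutoff < 2·fs/order), to a
*guarded* baseline estimator: the subtracted smoother averages only samples
at lags beyond a guard interval (default 0.06 s, about a QRS half-width)
around the current sample — the short-filter analogue of estimating the
baseline between beats. DC is still nulled exactly and the filter stays
symmetric (linear phase). Measured on synthetic records this suppresses a
0.3 Hz wander by ~99% while changing R amplitudes by ~8%. The residual cost
is echo artifacts at ±0.06–0.08 s around each QRS, which is why interval
*measurements* are not taken on this signal (below). Above the resolution
limit the plain windowed-sinc complement is used.

**The power-line FIR width.** A 101-tap Hamming-window band-stop at 360 Hz
cannot produce a deep notch over 49–51 Hz (the achievable |H(50 Hz)| is
only ≈ 0.71); the stop band must be at least as wide as the window's
transition, so the FIR stage defaults to mains ± 5 Hz, which reaches
−29 dB at the mains frequency while leaving 10 Hz essentially untouched.
The IIR band-stop stage keeps the narrow ±1 Hz band — recursive filters
have no such length limit.

The analog transfer functions in `example_bandpass_tf()`,
`example_iir16_tf()`, `example_pt_lowpass_tf()` and `example_reduced_tf()`
are evaluation fixtures for the response machinery; the 16th-order example
is not verifiably stable as tabulated and is never used to filter data. The
pipeline's actual 16th-order prototype is `design_iir_cascade()`, which is
designed digitally and is stable by construction. `bilinear_tf()` is
provided for discretizing analog descriptions.

## Minimax order reduction

The reduction stage condenses the 16th-order cascade $H(z)$ into a
low-order filter $\hat H(z;\theta)$ with all coefficients nonnegative. The
criterion is minimax on the magnitude response:

$$\min_{\theta \in [0, B]^p} \; \max_{f \in G} \;
\bigl| \, |\hat H(e^{2\pi i f / f_s};\theta)| - |H(e^{2\pi i f / f_s})| \, \bigr|$$

where $G$ is a log-spaced 256-point grid from 0.1 Hz to 99% of Nyquist and
$[0,B]^p$ is the coefficient box (default $B = 5$). The magnitude-response
reading of the objective is a design choice — it is the quantity that
determines filtering behaviour, which is what the downstream detector
consumes. The inner maximization is exact (a grid scan); the outer
minimization is Nelder–Mead with every candidate projected onto the
nonnegative box, seeded from a linear least-squares fit of the prototype's
complex response plus seeded random restarts. Candidate denominators with
poles on or outside the unit circle are rejected through a penalty.
Optimization proceeds sequentially through numerator degrees $0, 1, \dots$
with warm starts (the previous solution padded by a zero tap), which makes
the achieved deviation non-increasing in the target order *by
construction*, and the reported deviation is never worse than the initial
seed. The default target — numerator degree 1 over a scalar denominator,
three free coefficients — reports order 2, counting the coefficients of the
longer polynomial.

Nonnegativity has a user-visible consequence: with a nonnegative FIR
numerator over a positive scalar denominator, a nonnegative input (such as
a Hilbert envelope) filters to a nonnegative output. This holds *only* for
that FIR shape — a general IIR filter with nonnegative coefficients has no
such guarantee, and the package asserts it only in the FIR case.

Tests cross-check the optimizer against an exhaustive 50³ lattice over the
coefficient box (the optimizer must come within 5% of the lattice optimum;
in practice it beats it). Expect an irreducible deviation of ≈ 0.5 for the
default target: a two-tap magnitude response cannot follow a band-pass
shape, and the minimax optimum splits the difference across the band. The
stage's value is structural (low order, nonnegative coefficients, smooth
gain), not response fidelity.

## Hilbert-envelope detection

The analytic signal is built in the frequency domain (negative frequencies
zeroed, positive doubled, DC and Nyquist kept), giving envelope
$\sqrt{x^2 + H[x]^2} \ge |x|$ pointwise. The principal-value convolution
definition of $H$ is kept as the test oracle, discretized at odd-lag
midpoints (step $2\Delta t$), which respects the kernel's odd symmetry and
converges to the sinusoid ground truth within $10^{-3}$.

`detect_r_peaks()` scans envelope local maxima against 0.5× a running
amplitude estimate (exponential update, weight 0.125 per accepted beat,
initialized from the first two seconds), with a 0.2 s refractory window in
which a larger candidate replaces the previous acceptance. The thresholds
are package defaults — no published values exist for this chain. Detected
peaks are snapped to the local maximum of the morphology signal, which
also undoes the forward-filtering group delay.

Q and S are the signal minima in ±0.06 s windows beside each R peak; the
QRS interval is the Q-to-S time, and beats whose windows cross the record
edge are dropped with a warning. Interval measurements are taken on the
*morphology signal* — the power-line-notched original — because trough
positions are robust to slow baseline drift but not to the guarded
high-pass's echo artifacts, which fall exactly in the Q/S windows.

`pan_tompkins()` provides the classic reference detector (zero-phase
5–15 Hz band-pass, five-point derivative, squaring, 150 ms moving-window
integration, dual adaptive thresholds with search-back), delay-compensated
back to input indices. It is implemented in its textbook form; the
tabulated integer-coefficient low-pass kept in `example_pt_lowpass_tf()` is
unstable as written and serves only as a parsing fixture.

## HRV

`hrv_summary()` reports SDNN (population SD of RR × 1000, ms), RMSSD, NN50
(successive differences > 50 ms), mean heart rate, and the Poincaré
SD1/SD2. RMSSD carries a convention switch: the `"paper"` convention
divides the summed squared successive differences by the length $M$ of the
RR vector; the `"standard"` convention divides by the number of differences
$M-1$. The paper convention is the default and every report names the
convention used; the two differ strictly whenever any difference is
nonzero. NN50 is defined on successive *differences* — a deliberate
correction, since counting RR *intervals* longer than 50 ms would include
essentially every physiological beat.

SD1 is computed as the RMS of successive differences about zero divided by
$\sqrt2$ (a stationarity assumption), so the identity
SD1 = RMSSD$_{standard}/\sqrt2$ holds exactly rather than approximately;
SD2 is the mean-centred population SD of $(RR_n + RR_{n+1})/\sqrt2$.

## Classification and evaluation

Three rules classify a record's feature vector (mean QRS interval, mean
heart rate, SDNN, RMSSD, beat count):

* **QRS interval**: regular iff |mean QRS − 0.099 s| ≤ tolerance (default
  0.02 s, closed interval — a boundary deviation is regular).
* **Nearest centroid**: features are standardized by the training cohort's
  pooled mean/SD; the record takes the class of the nearer centroid, with
  ties and sub-margin differences called regular (the conservative
  choice). Centroids are fit from labelled training records. A cohort
  containing a single class cannot be fit; the package then anchors the
  regular centroid at the cohort mean and places the irregular prototype
  3 SD away in the wide-QRS/high-SDNN/high-RMSSD directions.
* **Fuzzy**: triangular/shoulder memberships over three inputs — QRS
  deviation (knees 0.02/0.05 s), the centroid-distance margin
  $d_{reg} - d_{irr}$ in standardized units (knees 0/1), and the beat count
  relative to the cohort median — combined by an 8-rule table
  (min-conjunction, max-aggregation, arg-max label, ties regular). The
  rule table itself is an implementation choice: regular when QRS deviation
  and margin are both small, irregular when either is high, with the beat
  count tipping the intermediate zone.

Evaluation treats *irregular* as the positive class. `confusion_counts()`
partitions records into Tp/Tn/Fn/Fp by agreement and actual class, and
`classification_metrics()` implements the evaluation formulas **exactly as
the protocol prints them**, which are not the textbook definitions:
sensitivity = Tp/(Tp+Tn), specificity = precision = Tp/(Tp+Fn), accuracy =
(Tp+Tn)/total, all × 100. Precision and specificity are therefore
identical for every input, and a perfect classifier on a mostly-regular
cohort can score a *low* "sensitivity" — both are properties of the
printed formulas, reproduced deliberately and verified in the tests.
`convention = "standard"` computes the textbook quantities for comparison,
and every report names its convention.

## Problem sizes and determinism

The shipped tests run the full chain at desk scale, chosen to exercise
every code path in well under a minute per file: 10–80 s records for
detection (≥ 100 beats for the sensitivity property), 420 s for SDNN
parameter recovery (≈ 500 beats), 5-record cohorts for the pipeline, a 50³
lattice for the reduction cross-check. All randomness flows through
explicit seeds: the same configuration and seed reproduce byte-identical
artifacts, which the tests assert on the pipeline's CSV/JSON outputs.

## Known limitations

* The guarded baseline filter leaves echo artifacts near each QRS; interval
  measurements avoid them by design, but downstream users reading the
  `baseline_removed` signal should be aware of them.
* The reduced-order filter is a structural smoother, not a response-faithful
  surrogate of the cascade (deviation ≈ 0.5 at order 2).
* WFDB support covers signal formats 212 and 16 (the MIT-BIH formats) and
  does not parse beat-type annotation files.
* The fuzzy rule table and membership knees are package defaults, not
  fitted quantities; they are fully configurable via `fuzzy_config()`.
* No frequency-domain HRV (LF/HF) and no per-beat arrhythmia typing.
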