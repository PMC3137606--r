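---
title: "Methods: simulating and analysing fetal responses to repetitive cord occlusions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing fetal responses to repetitive cord occlusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `fetaluco`: a pipeline for studying the fetal
electrocortical (ECOG) and cardiovascular response to labour-like
repetitive umbilical cord occlusions (UCO), driven by a synthetic cohort
generator calibrated so that the *processed* pipeline output — not the
latent parameters — reproduces the cohort statistics of the near-term
ovine preparation.

## The experimental template

Each virtual subject is recorded through a baseline period (default 60
min), then a mild UCO series (1-min occlusion every 5 min for 1 h), a
10-min occlusion-free period, a moderate series (every 3 min for 1 h),
another 10-min period, and a severe series (every 2 min) that continues
until an arterial blood sample measures pH < 7.00, after which ~10 min of
recording are retained. Blood samples are drawn at mid-baseline, at the end
of the first occlusion of each series, ~5 min after each series, between
occlusions at ~20 and ~40 min of the moderate series, and every ~20 min of
the severe series (snapped to the midpoint of an inter-occlusion gap). The
20-min severe sampling grid extends the published ~20/~40-min schedule:
severe series lasting up to ~100 min need later samples for the stop rule
to operate.

The decision to stop is taken on *measured* samples (latent pH plus 0.005
measurement noise), exactly as the experimental protocol stopped on a
measured value; the latent crossing time is kept as ground truth.

## Acidemia trajectory

The latent pH trend is piecewise: flat baseline (population mean 7.36,
between-subject SD 0.032); a shallow linear decline over the mild series
(net 0.035 units); partial recovery (+0.008, +0.015) in the occlusion-free
gaps; a convex decline over the moderate series (net 0.133 units, exponent
1.7, so most of the drop arrives late); and a power-law decline (exponent
1.2) through the severe series reaching 7.00 at a per-subject latent
crossing time drawn lognormally (median 30 min, log-SD 0.4, clipped to
18–95 min). A per-subject severity factor (lognormal, log-SD 0.15) scales
the mild/moderate drops. With probability 0.2 a subject's moderate decline
is deepened so the target is reached near the post-moderate sample,
emulating the minority of animals that never need a severe series.
Per-occlusion transient dips (ramp during the occlusion, exponential
recovery, τ = 100 s; amplitude 0.035–0.045 by series) ride on the trend, so
samples drawn at the end of a first occlusion sit visibly below it. After
the stop, pH declines a further ~5 min at half the terminal rate (lactate
washout) before recovering exponentially toward 7.18.

These constants were chosen once so that the sampled trajectory reproduces
the published sampling-phase values (baseline 7.36, ~6.90 five minutes
after the severe series) and the 20–100-min spread of severe-series
durations; they are not adjusted per run.

## Cardiovascular model

The arterial channel is a phase-warped pulse waveform riding on latent
mean-pressure and heart-rate paths; the amniotic channel is a slow
low-amplitude offset (10 mmHg + 0.9-mHz sinusoid + OU noise), and
`compute_abp()` recovers arterial-minus-amniotic pressure exactly.

**Heart rate.** Baseline per subject ~N(163, 15.8) bpm. Each occlusion
triggers a deceleration: 2–5 s chemoreflex delay, smooth fall over ~15 s,
then a slight continued drift downward (12% of depth per minute) so the
true minimum sits at the end of the occlusion, 2–8 s after cuff release —
the nadir timing reported for this preparation — followed by exponential
recovery (τ = 12 s). Per-occlusion nadirs are N(subject nadir, 2.5) around
a subject mean ~N(80, 6.3) bpm. Two OU noise processes (τ = 60 s, SD 3 bpm;
τ = 2 s, SD 2.5 bpm) are damped by 80% at the deceleration trough,
mirroring the reduced variability of deep vagal bradycardia — and, less
loftily, keeping the extracted minimum an unbiased estimate of the latent
nadir.

**Pressure.** Baseline per subject ~N(45, 12.6) mmHg. Before the subject's
hypotension onset, each occlusion produces a rounded hypertensive bump
peaking ~35 s in and easing ~8% by release. The subject's occlusion peak is
drawn as `64 + 0.35 × (baseline − 45) + N(0, 3.2)` mmHg: the occlusion
maximum tracks the subject's baseline only partially, reflecting the
vasoconstrictive ceiling that makes peak pressures far more tightly
clustered across animals than baselines (the published per-series maxima
have roughly a third of the baseline's spread). After the hypotension
onset, the early rise is no longer sustained: pressure falls from ~30 s
into the occlusion to 4–14 mmHg *below* baseline at release, deepening over
~20 min. The pulse is an asymmetric raised-cosine template (systolic rise
30% of the cycle, amplitude 18 mmHg) rendered by integrating the
instantaneous rate, so systolic peaks are unambiguous for the
peak-triggered FHR extraction.

Event-locked pressure features are computed on a pulse-averaged series (3-s
moving mean, 10 Hz): the calibration constants are mean-pressure
excursions, and a raw-waveform maximum would add half the pulse amplitude
to every occlusion maximum.

## Electrocortical model

ECOG is piecewise-stationary coloured Gaussian noise with trapezoidal power
spectra (flat to an edge frequency, cosine roll-off of 25% width),
synthesised by FFT shaping and joined with 0.5-s equal-power crossfades so
no broadband discontinuities contaminate the spectral analysis.

**Behavioural states.** Outside occlusions the spectrum alternates between
a high-voltage/low-frequency state (95% SEF target 7.5 Hz, amplitude ratio
2.1 vs the low-voltage state) and a low-voltage/high-frequency state, with
gamma-distributed epoch durations (shape 4; means 5 and 8 min). The state
pair is derived from the configured baseline means (88 µV amplitude,
14.4 Hz SEF) through the occupancy weights, so the baseline mixture is
calibrated by construction. Epoch means shift moderately toward the
high-voltage state as pH falls. Mean epoch lengths are free parameters of
the simulator (state cyclicity is documented for this preparation, but not
its durations); the gamma shape keeps per-subject occupancy stable enough
that a 10-subject cohort mean SEF lands within a few tenths of a hertz.

**Calibration against the pipeline.** Every regime's spectral edge is
chosen so that the *observed* SEF — after the 4th-order zero-phase
Butterworth band-pass (|H|⁴ on power), FFT resampling to 100 Hz, Welch
estimation with 2-s Hann segments, and upward bin quantisation (+0.25 Hz on
average) — equals the target. A per-rate calibration table inverts the
edge→observed-SEF map (`analytic_sef()` exposes the underlying numerical
quantile). Amplitudes are corrected by the corresponding power attenuation
factor. This is what makes round-trip recovery a meaningful test: the
generator never writes the target numbers anywhere; the pipeline has to
measure them.

**Occlusion response.** During each occlusion the current state's spectrum
is suppressed in proportion to acidemia: amplitude by up to 55% and SEF by
up to 58% (linear ramps in pH anchored at 7.30/7.33, flat above). Between
occlusions SEF is suppressed much more mildly (≤ 10%), so the
prior-vs-during SEF difference widens as pH falls — the delta-SEF
correlation with pH then carries the expected negative sign. After the
subject's spiking-onset time, each occlusion ends with a burst of
high-frequency activity lasting 15–20 s (SEF target per subject ~N(23, 4)
Hz, clipped below the band edge; amplitude 68% of baseline), after which
the SEF collapses to the 3 Hz floor for ~25 s (high-voltage, 125% of
baseline amplitude) before partially recovering ahead of the next
occlusion. The floor persists ~3 min past the final occlusion.

**Onset coupling.** Spiking and hypotension onsets are drawn in the pH
domain: spiking at ~N(7.24, 0.06) (clipped to 7.08–7.31), hypotension at a
mean 0.02 pH units later with correlation 0.9, both mapped to times through
the subject's latent trend. The clip keeps onsets inside the
moderate/severe window of every trajectory; lead times then span roughly
25–95 min with a mean near 50. Because both onsets and the crossing time
share the same trajectory, the spiking and hypotension lead times are
strongly correlated across subjects (R ≈ 0.85–0.9 in a 30-subject cohort).

## Processing conventions

- **ECOG preprocessing:** 4th-order Butterworth 0.3–30 Hz applied
  forward–backward (zero phase), then FFT-domain resampling to exactly
  100 Hz (exact for band-limited signals and correct for non-integer rate
  ratios; the 30 Hz band-pass is the anti-alias filter). Output length is
  `floor(n × 100 / fs)`.
- **Windows:** non-overlapping, half-open `[t, t+4)` s, stamped at centers;
  trailing partial windows discarded. Welch spectra average all 2-s Hann
  segments at 50% overlap within the window (three per 4-s window),
  giving 0.5 Hz resolution.
- **SEF:** cumulative power restricted to 0.3–30 Hz so the edge is
  invariant to out-of-band leakage; reported at the first bin reaching the
  95% quantile.
- **Amplitude:** 97.5th − 2.5th percentile of the windowed signal. The
  published analyses never define "voltage amplitude"; the percentile range
  tracks mean peak-to-peak excursion while ignoring isolated spikes, and is
  3.92σ for Gaussian signals. This convention is flagged in the output
  metadata.
- **FHR:** systolic peaks on the 1-s-detrended pulsatile ABP above a 5 mmHg
  prominence threshold, sub-sample refined by parabolic interpolation;
  rate 60/interval stamped at the earlier beat. Intervals outside
  [0.12, 1.5] s or above 1.75× the running median are rejected and
  interpolated across (flagged); silent spans ≥ 10 s remain gaps. Peaks
  within 1 s of the trace edges are dropped (the detrending window is
  truncated there). On noiseless trains the extraction is exact to well
  under 0.5 bpm across 60–240 bpm.
- **Event windows:** FHR nadir searched in `[start, end + 60 s]`;
  deceleration onset is the first time FHR stays 15 bpm below baseline for
  5 s (a clinical variable-deceleration convention; both numbers are
  parameters); ECOG deceleration means cover `[onset, onset + 60 s)` with
  `[start, start + 60 s)` as the no-deceleration fallback; ABP maximum is
  searched to 30 s past release (configurable — whether the post-release
  overshoot belongs in the maximum is genuinely ambiguous); ABP at the
  nadir is a ±2 s average to suppress beat-scale noise. Features whose
  windows lose more than half their data are reported missing, never
  imputed, and aggregates drop them pairwise.

## Onset detectors

In the experimental preparation the pattern was recognised visually. The
operationalisation here
declares an occlusion a *spike event* when its deceleration-end SEF peak
(max window in `[end − 20, end + 20]` s) reaches 15 Hz **and** the
following inter-deceleration SEF trough falls to 6 Hz; the onset is the
first event of the earliest run of ≥ 3 consecutive spike events that
persists to the end of the session (the pattern, once initiated, continued
in every animal). The thresholds sit roughly midway between the baseline
SEF (14.4 Hz) and the burst peak (23 Hz), and between the floor (3 Hz) and
the baseline; persistence of 3 guards against single-window flukes. All
three are exposed parameters and echoed in the outputs, since other
admissible readings of "abrupt increase" exist. The hypotension detector
applies the same run logic to "ABP at the FHR nadir ≤ the 30-s
pre-occlusion mean" (tolerance 0 mmHg, configurable). Lead times are
measured to the first *sample* below pH 7.00, mirroring the experiment's
decision rule.

Detection error is bounded by event spacing: an onset falling inside a
10-min occlusion-free gap cannot be detected before the next series
begins, which is why detector accuracy is assessed as "within one
inter-occlusion period".

## Statistics

Per-condition normality is assessed with a Lilliefors-type
Kolmogorov–Smirnov test (moments estimated; fewer than 5 values or zero
variance counts as non-normal). Normal measures: one-way repeated-measures
ANOVA with Bonferroni-corrected paired t post-hocs vs baseline. Non-normal:
Friedman rank test with Wilcoxon signed-rank post-hocs vs baseline under
Holm step-down correction (standing in for the rank-based
Student–Newman–Keuls procedure traditional in this design, which is
under-specified for rank post-hocs; the choice is recorded in the report). Subjects with missing cells are excluded listwise per measure.
Both omnibus tests are also available as within-subject label-permutation
tests (`perm_test_repeated()`), which is how they are validated against
brute-force oracles. Correlations pool the 10-min interval summaries across
subjects (the within-animal-first variant can be obtained by stratifying
the input); the method is auto-selected by marginal normality.

## Problem sizes and reproducibility

Default synthesis runs at 250 Hz for both pressure and raw ECOG — pressure
peak detection is rate-robust with sub-sample refinement, and ECOG is
band-limited to 30 Hz long before the 125 Hz Nyquist — with ECOG processed
at 100 Hz; a 10-subject cohort (~3.5 simulated hours each) simulates and
analyses in about a minute. The onset-correlation analysis uses a
30-subject cohort with a 20-min baseline, since baseline length does not
enter lead times. One master seed drives everything: cohort-level traits
are drawn by permuted-quantile (stratified) normal sampling, so a small
virtual cohort is representative of its population means while keeping
between-subject SDs at the values implied by the published SEMs; per-subject
waveform noise comes from fixed-offset child streams. Identical
configuration and seed give bit-identical cohorts.

## What the simulator does and does not emulate

It emulates: the three-series protocol and stop rule; progressive acidemia
with per-occlusion transients and partial recovery; chemoreflex
decelerations with end-of-occlusion nadirs; the biphasic
hypertensive–hypotensive pressure evolution; ECOG state alternation with
acidemia-dependent occupancy; occlusion-phase ECOG suppression; and the
late SEF burst/floor signature with coupled hypotension timing.

It does not emulate: waveform morphology beyond a fixed pulse template (no
dicrotic notch, no respiratory modulation); ECG (recorded but never
analysed in this preparation); electrode dropout or channel loss (reported ECOG statistics for this
preparation rest on 8 of 10 animals — the simulator keeps all channels; missing-data handling is still exercised through window-coverage
rules); seizure-like activity; haemodynamic mechanism (paths are
phenomenological, not an ODE chemoreflex model); or blood-gas chemistry
beyond pH, pO₂, pCO₂ and O₂ saturation trajectories. Consequently, passing
round-trip tests demonstrates that the *pipeline* is correct and its
conventions self-consistent — not that the detectors would achieve the same
accuracy on real recordings, where artifact structure and
between-preparation variability are richer.
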