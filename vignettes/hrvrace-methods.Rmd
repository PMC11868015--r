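---
title: "Methods: simulating and analysing post-exercise HRV and haemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing post-exercise HRV and haemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`hrvrace` implements, end to end, the measurement chain used to compare
cardiovascular responses to strenuous endurance exercise between riders with
and without coronary artery calcification (CAC): beat-to-beat RR intervals
recorded by a chest strap during a race are cleaned of beat artifacts,
ultra-short-term heart rate variability (HRV) is quantified over the 5
minutes following a brief measurement stop at the top of the hardest climb,
haemodynamic indices (heart-rate reserve and recovery, pulse pressure,
rate-pressure products) are derived from the RR stream and manual blood
pressure readings, and the two groups are compared non-parametrically with a
multivariable logistic model on top. Because the participant-level data of
such studies are not publicly deposited, the package ships a first-class
synthetic-data module that generates cohorts with the published group-level
statistical structure, including known-truth beat artifacts, so that every
stage of the chain can be validated quantitatively.

```{r, eval = FALSE}
library(hrvrace)
coh <- simulate_cohort(generate_cohort(cohort_config(seed = 1)))
rep <- run_full_analysis(coh)
print(rep)
```

# Synthetic cohorts

`generate_cohort()` draws per-subject metadata and latent physiology from
per-group distributions parameterised directly by published medians and
interquartile ranges (`default_group_params()`). Two distributional
families are used:

* **Log-normal** for strictly positive, right-skewed quantities — the HRV
  band powers (ms²) and lactate (mmol/L). Parameters are solved from the
  printed quartiles on the log scale: `meanlog = log(median)`,
  `sdlog = (log q75 − log q25) / (2 Φ⁻¹(0.75))`. Band powers are truncated
  at physiological ceilings (VLF 2000, LF 300, HF 100 ms²; each around the
  99.7th percentile of its law) because the unbounded log-normal tail
  occasionally implies beat modulations no post-exercise tachogram at
  RR ≈ 400 ms could carry.
* **Normal** (truncated at physiological bounds, e.g. blood pressure in
  [30, 320] mmHg) for everything else, with `sd = IQR / 1.349` and the
  median as centre.

This matches the median (IQR) reporting convention of the emulated study;
sampled group medians converge to the configured targets (tested at
n = 500/group).

Start and hill-top blood pressures are drawn from their own printed
distributions, coupled by a shared latent with correlation 0.5, so the
systolic rise from start to hill-top is positive in essentially every draw
while both marginals match their tables. A consequence worth knowing: the
median of the derived start-to-top *delta* is close to, but not exactly,
the printed delta rows — medians are not additive, and the printed tables
themselves carry the same inconsistency.

Choices the tables do not pin down, made once and kept:

* **Smoking prevalence** is used in the adjusted logistic model but never
  printed; 10% per group is a realistic figure for a middle-aged endurance
  cohort.
* **Artifact prevalence** of chest-strap RR recordings during vigorous
  exercise is not reported; the default injection rate is 2% of beats,
  typical for this sensor class in field conditions.
* **Broadband beat noise** defaults to 3 ms, which reproduces the published
  post-stop RMSSD scale (≈ 4.4 ms).
* **Walkers** (riders who dismount on the climb): the published fractions
  (6/31 and 6/25) are the defaults, with selection weighted towards low
  VO2max, mirroring the reported fitness gap between walkers and cyclists.

## Beat generation

RR series are generated by integral pulse frequency modulation (IPFM,
`ipfm_tachogram()`): the instantaneous rate `1000 / rr(t)` is integrated
and a beat is emitted at each unit crossing. This produces genuinely
unevenly spaced beats, so the even-resampling step of the spectral analysis
is exercised on realistic input rather than on data that were regular to
begin with.

The instantaneous RR signal is a piecewise HR trajectory (baseline riding →
linear climb to the per-subject peak fraction of laboratory maximum HR →
mono-exponential decay during the stop → easy riding) plus one sinusoid per
HRV band whose amplitude encodes the subject's latent band power
(`A = sqrt(2 P)`). The recovery decay is parameterised by the 30-s HR drop
(the statistic the study reports) with a default time constant of 60 s; the
study gives only the 30-s drop, not the functional form, and a single
exponential with this constant is a standard post-exercise model. Two
consequences are documented rather than tuned away:

* The recovery transient dominates the measured VLF band (it adds roughly
  100 ms² after linear detrending), so *measured* VLF exceeds the latent
  VLF target. This mirrors real post-exercise recordings; LF leakage from
  the transient is small (≈ 1–2 ms²).
* The mono-exponential decay towards a plateau yields a mean stop HR a few
  bpm above the printed stop means; no analysis step depends on this.

Artifact injection (`inject_artifacts()`) corrupts a configurable fraction
of beats at non-adjacent sites with three mechanisms — merged intervals
(missed beat), split intervals (extra detection), and ectopic-like
shorten/lengthen pairs — all exactly conserving total recording time, and
returns the ground-truth site list for sensitivity scoring.

# Preprocessing

Detection follows the percentage-threshold median filter: beat *i* is
flagged when its interval deviates from the median of its surrounding
window by more than 5% of that median. The window is 11 beats (5 per side;
the published method fixes only the threshold, and beat-count windows of
this order are common practice), truncated at the edges, and the centre
beat is excluded from its own median so a large artifact cannot mask
itself. The windowed median is computed in C++ (`std::nth_element`) since
it sits inside every simulation replicate.

Corrections (`apply_correction()`): `none`, `deletion` (with re-timing of
survivors), `linear` and natural-cubic-spline interpolation of RR against
beat time over unflagged neighbours (consecutive flags are corrected as one
span), and `arima` — each flagged run is replaced by forecasts from an
ARIMA(1,1,1) model fitted on the most recent ≥ 60 preceding unflagged beats
(conditional-sum-of-squares estimation; order configurable), with an
automatic, logged fallback to linear interpolation when the preceding run
is short or the fit fails. Interpolation-family corrections keep the
original beat timestamps — the beats occurred when they occurred; only the
interval values are repaired — so unflagged beats are untouched except
under deletion.

# HRV metrics

RMSSD and SDNN (sample SD, n − 1) are computed on the corrected beat series
inside the analysis window (the 5 minutes following, and including, the
stop; a logged note is emitted below 90 s of coverage, the reliability
floor for ultra-short-term LF). Spectral powers are computed on a 4 Hz
natural-cubic-spline resampling of the tachogram (Nyquist 2 Hz, far above
the 0.4 Hz band edge; rate configurable), after removal of mean and linear
trend, with a single-segment FFT periodogram and no taper. Welch averaging
is deliberately not used: a 5-minute window leaves too few segments for the
0.04 Hz resolution the LF band needs. Band powers are sums of periodogram
ordinates over VLF (0, 0.04], LF (0.04, 0.15], HF (0.15, 0.4] Hz —
lower-exclusive/upper-inclusive so no bin is double-counted, with the zero
bin excluded (detrending removes DC, so the nominal "0–0.04" band starts at
the first positive frequency). `tp = vlf + lf + hf` holds exactly by
construction, and the band sum matches the detrended variance up to
leakage above 0.4 Hz (tested at 10%).

# Haemodynamics

HR at a time point is a 5-s centred mean of the linearly interpolated
instantaneous HR (beat-level HR at an instant is noisy, and the estimator
is otherwise unspecified); HR recovery is the difference of such means at
the stop and 30 s later. The uphill maximum uses a 5-s rolling mean.
Percent-of-max columns are relative to the laboratory VO2max-test maximum;
HR reserve is `(HR − HR_rest) / (HR_max,lab − HR_rest)`. Rate-pressure
products pair the single hill-top systolic pressure with the uphill maximum
HR (`rpp_max`) and the stop-mean HR (`rpp_mean`) — pressure is measured
manually after stopping, not instantaneously at peak effort, and no delay
correction is attempted. Lactate triplicates are aggregated as the mean of
the two closest values; the exact tie-break is unspecified in the source
convention, so equal gaps resolve to the lower-mean pair, with a logged
note.

# Group statistics

All table cells are type-7 (linear-interpolation) quantiles. The
Mann-Whitney test reports the first-listed (CAC-free) group's U — the
convention consistent with the published LF row, where U = 510 exceeds
n₁n₂/2 = 387.5 while the CAC-free median is larger — with an exact
two-sided p (via the exact null distribution) for tie-free samples of
combined size ≤ 16 and otherwise a normal approximation with tie correction
and 0.5 continuity correction. The 2×2 chi-square uses the Yates continuity
correction, which reproduces the published sex-distribution p of 0.468
(the uncorrected statistic gives ≈ 0.30). The logistic layer is a plain
maximum-likelihood fit with Wald 95% CIs (`exp(coef ± 1.96 SE)`) on
untransformed predictors, matching per-unit odds ratios; complete
separation is flagged and the affected OR withheld. Significance is
two-tailed at 0.05 with no multiple-testing correction, because the
emulated analysis applies none. Walker detection declares a rider
dismounted when power stays at 0 W (or, without a power meter, speed stays
below 1.8 m/s — a documented guess exposed in the configuration) for a
contiguous run covering at least 20% of the climb.

# Pipeline

`run_full_analysis()` chains preprocessing (default: ARIMA correction at
the 5% threshold, the configuration behind the published HRV table), HRV,
haemodynamics and the comparison layer, and fits two logistic models: the
hill-top model (LF, systolic/diastolic hill-top pressure, diastolic and
pulse-pressure deltas, mean RPP) and the expanded adjusted model (LF plus
age, sex, BMI, maximum HR, VO2max, smoking, resting pressures, diastolic
delta). Missing cells propagate as missing (complete-case logistic
regression). `correction_sensitivity()` re-runs the LF comparison under
all five correction methods on the full cohort and the cyclists-only
subset. Reports are deterministic given the cohort and configuration; the
only randomness in the package lives in the simulator, governed by the
cohort seed (default 20180421, recorded in the configuration).

# What the simulations do and do not show

The generator reproduces the *group-level statistical structure* of the
emulated study — sample sizes, medians/IQRs, event timing, artifact
plumbing — under idealised assumptions: stationary sinusoidal band
modulation, a smooth deterministic HR trajectory, white per-beat noise, and
artifacts that are exactly merged/split/shifted intervals. Real recordings
have drifting modulation frequencies, respiration coupling, movement
artifacts with richer signatures, and no ground truth. Passing tests
therefore validate the computational chain (detection operating
characteristics, spectral calibration, estimator correctness, test
calibration), not the physiology; pre-race HRV is not calibrated at all
because no within-subject baseline HRV is published.

Problem sizes used by the validation suites were chosen to give stable
statistics at interactive runtimes: 50-seed medians for artifact
round-trip fidelity, 500 replicates at n = 2000 for logistic coverage,
200 difference-free cohort runs (pooled over ~40 variables) for null
calibration, and 50 seeds at n = 100/group for LF-effect detection; the
acceptance script reports the same quantities at moderately reduced
replication.

# Known limitations

* The IPFM beat series samples the modulation at beat resolution, so very
  high HF frequencies approach the beat Nyquist during slow-HR segments.
* Measured VLF is transient-dominated (above); comparisons of VLF between
  groups remain valid since both groups share the trajectory model.
* ARIMA correction forecasts from the past only (no backcasting); for gaps
  at the very start of a recording it falls back to interpolation.
* The cyclists-only logistic model is computable but makes no claim of
  matching any published analogue, which exists only for the full cohort.
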