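---
title: "Cardiorespiratory coupling: models, parameters and validation design"
author: "crcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiorespiratory coupling: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the signal models, the estimators, the tunable parameters with their
defaults and rationale, what the synthetic-data generator does and does
not emulate, and the numerical and design choices that were genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Respiratory sinus arrhythmia (RSA) — the vagally mediated speeding of
the heart on inspiration and slowing on expiration — is the workhorse
index of parasympathetic cardiac control. The standard way to measure it
is high-frequency (HF) spectral power of the RR-interval series, with HF
defined as 0.15–0.4 Hz. That definition presumes adult breathing rates.
Preterm infants breathe at 0.7–1 Hz with heart rates of 140–160 bpm, so
adult-band HF power is blind to their RSA; even the widened infant band
(0.2–1.5 Hz) mixes RSA with everything else in a 1.3 Hz span. The
package therefore implements, alongside band powers, coupling measures
that use the respiration signal itself: the orthogonal-subspace
statistic Px, mean phase coherence, bivariate phase-rectified signal
averaging, and magnitude-squared coherence — applicable to both
populations on the same footing, across a pre / stimulus / post
protocol.

## Preprocessing

**RR series.** `rr_from_peaks()` takes first differences of strictly
increasing R-peak times. `correct_artifacts()` replaces manual artifact
editing with a deterministic rule: an interval deviating more than
`tol = 0.25` (relative) from the median of its 11 surrounding intervals
is replaced by natural-cubic-spline interpolation of the unflagged
neighbours; a window with more than 20 % flagged intervals is rejected.
Both thresholds are configurable; 25 % sits between typical ectopy
(≥ 40 % deviation) and ordinary variability (≤ 10 %).

**Detrending.** `detrend_smoothness_priors()` removes slow trends by
regularised least squares: the trend is `(I + λ²D₂ᵀD₂)⁻¹y` with `D₂`
the second-difference operator and `λ = 500`. Constants and linear
ramps are in the null space of `D₂` and are removed exactly; at 4 Hz
the equivalent high-pass cutoff is near 0.035 Hz, below both
populations' LF bands. The solve uses a sparse Cholesky factorisation;
the test suite checks it against the explicit dense-matrix form to
1e−8 relative and checks linearity to 1e−10.

Detrending is applied to the *beat-domain* RR sequence, then the result
is spline-resampled to 4 Hz (`resample_rri()`), each interval
timestamped at its closing beat. Applying λ = 500 in the beat domain
(mean adult beat ≈ 0.86 s) rather than to the 4 Hz samples shifts the
effective cutoff by the beat-rate/4 Hz ratio; with the analysis bands
starting at 0.02–0.04 Hz either choice leaves the bands intact, and the
beat-domain order matches a reading of the processing chain in which
detrending precedes interpolation.

**Respiration.** Two paths share the 0.05–2 Hz zero-phase Butterworth
band-pass (applied as a 5th-order high-pass plus 5th-order low-pass
cascade — the direct order-10 band-pass recursion is numerically
unstable at a 0.003 relative band edge), resampling to 4 Hz, and
z-scoring:

* `preprocess_infant_resp()` additionally subtracts a centred 1.2 s
  running-median baseline after anti-alias downsampling to 16 Hz. The
  1.2 s window is almost exactly one infant breath (0.85 Hz), so the
  median tracks the baseline while cancelling over each cycle.
* `preprocess_adult_resp()` omits the median step. At adult rates
  (≈ 4 s per breath) a 1.2 s median tracks the waveform itself and
  injects harmonic and intermodulation distortion — empirically this
  distortion was the dominant source of spurious coupling asymmetry in
  the directionality null experiments, which is why the adult path
  exists at all. The 0.05 Hz high-pass already removes baseline drift.

All zero-phase (forward–backward) filtering is deliberate: the phase
and lag sensitive analyses downstream (MPC, BPRSA) must not inherit
filter phase distortion.

**ECG-derived respiration.** For adults without a respiration channel,
`ecg_derived_respiration()` chains a 0.8 Hz high-pass and 30 Hz
low-pass (order 12, zero-phase, run as cascaded order-4 sections), a
derivative-square-integrate R-peak detector (refractory 0.25 s adult /
0.18 s infant), the slope-range series — per beat, max minus min of the
central-difference derivative within ±50 ms of the R peak — an
11-beat running-median ± 3 MAD outlier rule, spline resampling to 4 Hz
and z-scoring. The ±50 ms QRS half-width reflects a typical ~100 ms QRS
duration; the outlier rule concretizes a correction procedure whose
details are not fixed by the method's definition. Both are exposed as
arguments.

## Spectral metrics

`welch_psd()` averages Hamming-tapered, mean-removed segments (default
60 s, 50 % overlap). These parameters are a design choice: they give
five averages per 3-minute window and Δf ≈ 0.017 Hz, enough to resolve
the adult LF band's lower edge at 0.04 Hz. Scaling satisfies Parseval
(integrated PSD ≈ variance), which the tests assert within 10 % on
white noise. Band powers are trapezoidal integrals over the
population's LF/HF bands; LF/HF is reported missing when HF power is
zero. PSD units are absolute power of the dimensionless detrended RRi
series — no attempt is made to reproduce any particular absolute scale.

`mean_msc()` computes Welch-averaged magnitude-squared coherence and
averages it over 0–2 Hz (the full Nyquist range of the 4 Hz grid). A
single-segment estimate is identically 1, so configurations with fewer
than 4 segments are refused.

## Orthogonal subspace projection and Px

Given respiration `x` and RRi `y` (both mean-removed), the delay matrix
`V` has columns `x` delayed by 0..m samples; `y`, aligned causally to
its last `N − m` samples, is split by orthogonal projection onto
`span(V)` into a respiration-related component and a residual. The
projection is computed by QR least squares rather than the explicit
`V(VᵀV)⁻¹Vᵀ` inverse (a rank-deficient `V` falls back to the
pseudoinverse with a warning); the dense normal-equations form is kept
as the *oracle* in the tests, where agreement to 1e−8 relative over 100
random instances is asserted. `Px = |y_x|²/|y|²` is the fraction of RRi
power in the respiratory subspace — a band-free RSA index.

Model order selection (`select_model_order()`) minimises
`MDL(m) = N ln σ²ₘ + (m+1) ln N` and `AIC(m) = N ln σ²ₘ + 2(m+1)` over
`m = 1..30` and takes the *smaller* of the two minimisers — the most
conservative reading of using both criteria; `criterion = "mdl"`
switches to MDL alone, and both traces are stored so alternative
penalties can be compared after the fact. Ties break to the smallest
order. Note that `m` counts *delays*: a filter using lags 0..2 is
ideally recovered as `m = 2`.

## Mean phase coherence

Phase of a broadband signal is ill-defined, so both series are
band-passed to the population's respiratory band (adult 0.1–0.5 Hz,
infant 0.3–1.5 Hz, 4th-order zero-phase Butterworth) before the
analytic-signal phase is taken; the band is a configurable design
choice, since the underlying method definition leaves pre-filtering
open. The first and last 5 s are flagged and excluded to suppress
boundary artifacts of the FFT-based analytic signal.
`mpc()` is the circular mean resultant length of the phase difference:
1 for perfect 1:1 locking, ≈ N^(−1/2) for independent phases (the tests
check < 0.15 at N = 720 in ≥ 95 % of draws). Only 1:1 locking is
considered; no n:m synchrogram analysis.

## BPRSA and coupling strength

Anchors on the *non-detrended* RRi branch mark heart-rate decelerations
(`x_i > x_{i−1}`, i.e. RR lengthening, with averaging horizon T = 1) or
accelerations; ties are excluded from both sets. Respiratory anchors are
the maximum and minimum of each cycle, cycles delimited by upward
zero-crossings of the z-scored signal with a minimum cycle length of
`0.5 / f_resp_max`. `prsa_curve()` averages 2L-sample windows (L = 55)
of the target around the anchors; anchor feasibility (full window inside
the series) is enforced at curve time, and a window with fewer than 10
anchors is deemed invalid.

Coupling strength scores the association between the trigger's own PRSA
curve and the target's BPRSA curve on the same anchors:

* `max_xcorr` — the maximum over lags (±half the curve length) of the
  absolute Pearson correlation of the overlapping curve segments. Per-lag
  normalisation makes a pure shift score exactly 1 at its lag and keeps
  the statistic in [0, 1] and affine-invariant.
* `mi` — a plug-in kernel-density mutual information estimate over the
  paired curve samples: product Gaussian kernels, Silverman bandwidths
  (`1.06 σ n^{−1/5}`), joint and marginal densities evaluated at the
  sample points, floored at 0 nats. Absolute MI levels from 110-point
  curves are biased upward, so only within-run comparisons (direction
  orderings, condition contrasts) are treated as meaningful.

`bprsa_panel()` emits the four-row panel — RRi→respiration under
acceleration/deceleration anchors and respiration→RRi under cycle
maxima/minima — that feeds the directionality test.

## Group statistics

Normality is screened with the Lilliefors test (`nortest::lillie.test`
behind `lilliefors_test()`); condition effects use the Friedman test
(`stats::friedman.test`) across pre/music/post, and — gated by default
on a significant omnibus — pairwise Wilcoxon signed-rank post-hocs with
Bonferroni ×3, zeros dropped, exact null for ≤ 25 untied pairs and the
continuity-corrected normal approximation otherwise.

The directionality test pools two paired slots per subject —
(acceleration vs cycle-maximum) and (deceleration vs cycle-minimum) —
into 2n pairs, applies a paired Wilcoxon with Bonferroni over the three
protocol phases, and names a winning direction only when the corrected
p falls below 0.05. With n = 18 subjects the statistic is bounded by
36·37/2 = 666, which the tests assert under forced dominance. This
(subject × anchor-slot) pairing is the only scheme whose statistic range
is consistent with cohort sizes of 18–19.

## The synthetic generator

`generate_subject()` builds three contiguous segments (pre ≥ 180 s,
stimulus 360 s, post ≥ 180 s) with per-condition gain multipliers, all
on an 8 Hz simulation grid:

* **Respiration** `r(t) = sin(φ(t))`, instantaneous frequency
  `resp_freq` modulated by a bounded random walk (5 %/min, clipped at
  ±20 %), plus observation noise.
* **Heart period** `T(t) = 60/hr_mean · (1 + rsa_gain·r(t) +
  lf_gain·sin(2π·0.095t + θ) + ε(t))`, clipped below at 0.25 s; beats
  are emitted by an IPFM integrator (the integral of `1/T` crossing
  integers, crossings located by linear interpolation). IPFM makes the
  respiration-related RR variance analytically bookkeepable, giving Px
  recovery a quantitative oracle.
* **Reverse influence** (`reverse_gain`) leaks the 0.5 Hz-low-passed
  cardiac fluctuation additively into respiration — a phenomenological
  stand-in for an immature-regulation regime with heart→respiration
  influence.
* **ECG** (optional): a stereotyped QRS template at each beat, amplitude
  modulated by `1 + 0.1·r(t)`, plus baseline wander and white noise at a
  requested SNR — just enough morphology for peak detection and the
  slope-range surrogate, nothing more.

Defaults are the study conditions: infants HR 140–160 bpm and
respiration 0.7–1.0 Hz, adults 60–80 bpm and 0.2–0.3 Hz;
`rsa_gain` 0.04 (adult) / 0.01 (infant) and `lf_gain` 0.06 / 0.03, which
place Px and LF/HF in the ranges reported for the two populations
(adult Px of order 0.2–0.5 and LF/HF of order 1–3; infant Px of order
0.01–0.06); `noise_sd` 0.03; `reverse_gain` 0; condition multipliers all
1, so the default protocol is a true null for the calibration tests,
with effects injected explicitly where a test simulates one.

**Noise spectra.** Two choices matter more than they look:

* RR modulation noise `ε(t)` is Gaussian noise low-passed at 0.1 Hz —
  residual LF-band autonomic variability — so a zero-RSA subject has
  *no* RR power anywhere in either population's respiratory range
  (including the slowest 0.2 Hz breathers).
* Respiration observation noise is white noise band-passed to
  0.15–1.5 Hz — in-band waveform irregularity; out-of-band sensor noise
  would be removed by the preprocessing band-pass anyway.

The rationale is structural. Both BPRSA anchor families are
quasi-periodic: respiratory anchors recur at the breathing rate, and
under an LF rhythm the RR anchors cluster at the LF rate. Anchor-locked
averaging retains, coherently, any *target*-signal power at the
trigger's recurrence frequency — so RR noise in the respiratory band
would register as spurious respiration→RR coupling, and respiration
noise in the LF band as spurious RR→respiration coupling, in a
generator that is nominally uncoupled. Keeping the two noise bands
disjoint removes both pickup channels, and makes "uncoupled" mean what
it should for every coupling metric at once. White and 1/f alternatives
were examined and rejected on exactly this ground.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: non-sinusoidal and apnoeic breathing
patterns, broadband (band-overlapping) HRV backgrounds, ectopy beyond
the injected artifact tests, movement artifacts, multi-lead ECG
morphology, and any true nonlinear coupling beyond the linear gain
terms. Recovery results transfer to real recordings only to the extent
that these features do not dominate.

## Windowing and orchestration

Three-minute windows: the final 180 s of the pre segment, three windows
tiling the 360 s stimulus with 50 % overlap (offsets 0/90/180 s — the
unique symmetric tiling; configurable), and the first 180 s of the post
segment; metric values from the stimulus windows are averaged.
`run_cohort()` applies the per-subject pipeline, assembles
subjects × conditions matrices per metric, runs the Friedman/Wilcoxon
layer and the per-condition directionality tests, and is deterministic
given the cohort seed (byte-identical serialized results across reruns,
asserted in the tests). Subjects failing a stage are excluded listwise
per metric without touching other subjects' values.

There is no shell entry point: the exported functions
(`generate_cohort()`, `analyze_subject()`, `run_cohort()`,
`cohort_stats()`, `cohort_directionality()`) are the interface, mapping
one-to-one onto the simulate / analyze / cohort / stats workflow.

## Numerical choices and degenerate inputs

* Smoothness-priors solve: sparse symmetric positive-definite solve; no
  dense inverse is ever formed.
* OSP: QR least squares; pseudoinverse fallback (with warning) on rank
  deficiency; both inputs mean-removed (`center = FALSE` exposes the raw
  textbook projection for already-centred signals).
* MDL/AIC: residual variance floored at machine epsilon before the log;
  ties to the smallest order.
* Constant series are rejected where a statistic is undefined (z-score,
  phase, normality test) and reported as missing where a row can be
  (zero-variance PRSA curves, zero HF power).
* Welch: each segment is mean-removed before tapering, so a constant
  series yields an identically zero PSD.
* Anchor ties (`x_i = x_{i−1}`, possible after resampling) belong to
  neither anchor set.

## Validation design and problem sizes

The acceptance layer (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) validates by oracle agreement and parameter
recovery, not by reproducing any published table — the recordings
behind published values are not available, so the package's claim is
that the *machinery* is correct and calibrated. Problem sizes were
chosen so the whole suite runs in minutes on one CPU: 100 random OSP
instances (N ≤ 500, m ≤ 10); Px recovery over the RSA-gain ladder
{0, 0.25, 0.5, 1} × 0.04 with 20 seeds per gain and population; 100
independent-phase draws for the MPC null and 20 seeds per jitter level;
20 replicate adult cohorts (n = 19) each for directionality recovery
and its uncoupled null; 1000 null replicates for the Friedman and
family-wise error rates; and a full 18-infant + 19-adult double run for
end-to-end determinism. The acceptance script uses the same designs at
somewhat smaller replicate counts and writes every quantity it computes
to JSON.
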