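---
title: "Models and methods behind hrvtrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hrvtrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hrvtrial` reproduces, on synthetic data with known ground truth, the full
cardiovascular-safety analysis of a two-arm auricular vagus nerve stimulation
(taVNS) trial in neurocritical care: continuous ECG and vitals over the ICU
stay, beat delineation, heart rate variability (HRV) and QTc metrics, daily
and session-locked aggregation, a factor decomposition of autonomic activity,
and the statistical layer. This vignette explains each model, the tunable
parameters and their defaults, what the synthetic generator does and does not
emulate, the numerical decisions, and the package's known limitations.

## Why synthetic data

The patient recordings such an analysis is normally run on cannot be shipped
with a package, and no public dataset provides multi-day ICU ECG with
per-beat ground truth. The package therefore treats the *generator* as a
first-class, tested module: every downstream stage is validated against
quantities the generator knows exactly (true fiducial samples, true SDNN /
RMSSD, true session intervals, true arm effects). Passing these tests shows
that the pipeline measures what it claims to measure on signals with the
stated structure; it does not show robustness to everything real ICU data
contains (see Limitations).

## The synthetic trial

**Study conditions.** Defaults mirror a 24-patient randomized trial: 11
active (taVNS) and 13 sham subjects; recording duration drawn per subject
from a normal distribution with mean 11.1 and SD 6.8 days (clipped to 3–13);
two 20-minute stimulation sessions per day; ECG nominally at 500 Hz and
vitals at 1 Hz. Arm effects are expressed as standardized shifts (Cohen's d)
of the active arm's change-from-day-1 and default to the pattern the analysis
is designed to detect: +0.42 on RMSSD, +0.10 on SDNN, −0.01 on heart rate,
−0.57 on QTc, −0.49 on the peripheral perfusion index (PPI), +0.37 on
respiration rate, 0 on blood and intracranial pressure. Daily PPI and
respiration changes are drawn with correlation −0.37 in the active arm and
−0.08 in the sham arm (vasodilation-compensation coupling). The acute
per-session heart-rate response follows a mixed model with coefficients
(intercept 0.73, arm −0.29, mRS change 1.47, arm × mRS −1.85 bpm) plus a
1 bpm subject random intercept and 2 bpm session noise.

**Day scaling.** A literal day would be 24 h × 500 Hz per subject-day —
billions of samples per trial. Each synthetic "day" is instead a continuous
recording of `day_duration_s` (default 9000 s) containing both sessions with
full 20-minute pre/post margins; daily metrics are computed over that
recording. This preserves every structural feature the analysis uses (two
sessions, a day-level reference distribution, coverage checking) at desk
scale. Raw ECG is rendered on demand by `synthesize_ecg()` rather than for
whole trials.

**RR model.** RR series are drawn from a two-band spectral model — Gaussian
spectral envelopes centered in the LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz)
bands, inverse-FFT with random phases — and the two band amplitudes are
solved (two Newton steps on the exact quadratic moment system of the
realization) so the *realized* SDNN and RMSSD hit their targets. This gives
independent control of overall variability and short-term vagal variability,
exactly the axes the factor analysis must separate. Because the model has no
power below the LF band or above the HF band, the achievable RMSSD/SDNN
ratio at mean interval Δ is bounded by the band geometry
(√(2(1−cos 2πfΔ)) at the band edges); trajectory draws outside that region
are clamped before rendering, and the ground-truth table records the
*realized* series metrics, not the nominal draw. Ectopic beats are injected
as 25–45% jumps from the previous interval and outliers as intervals
> 2 s or < 300 ms, each with exact truth labels.

**ECG model.** Each beat is a fixed template of Gaussian bumps (P, Q, R, S,
T) stretched per beat; wave onsets/offsets are defined at 2.5 SD from each
bump center, so all fiducials are known analytically. The T bump is placed so
that QT (QRS onset to T offset) equals the prescribed per-beat QT — with
`qt_fun = a·√RR` every beat has Bazett QTc exactly `a`. Exact, analytically
known fiducials were preferred over morphological realism: they make
delineation error measurable to the sample.

**Vitals and events.** Vitals are AR(1) processes (lag-1 coefficient 0.99)
around the day's true mean. The treatment-event trace is a rectangular pulse
train with additive Gaussian noise (SD 0.08 of the pulse amplitude, safely
below the half-maximum threshold). Sessions sit at two fixed slots per day
with ±5 min uniform jitter, since no clock schedule is prescribed. Monitoring
gaps ("cyclical restarting") remove beats in random ~90 s windows totalling
`gap_fraction` of the day.

All randomness flows from one root seed; a fixed spec reproduces the dataset
bit for bit.

## ECG processing

Filtering is a fifth-order 0.5 Hz Butterworth high-pass followed by a
second-order 60 Hz notch (Q = 30), both applied forward–backward so fiducial
timing is preserved (zero phase). Gap-free segments are filtered
independently; gaps are never interpolated, and segments shorter than 2 s are
excluded as un-filterable.

R peaks are detected from the steepness of the absolute signal gradient: the
smoothed absolute gradient (80 ms window) is compared against a slow average
(750 ms); supra-threshold episodes (weight 1.35) longer than 0.4× the mean
episode length are QRS complexes; the R peak is the in-episode signal
maximum; a 200 ms refractory period (physiological upper rate bound) keeps
the larger of any closer pair. The smoothing window and threshold weight were
calibrated on template ECG so that clean-signal sensitivity and precision
exceed 99.5% and remain ≥ 99% at 10 dB SNR.

Delineation uses the quadratic-spline dyadic wavelet (the classic
modulus-maxima ECG delineator family), computed in the frequency domain with
the accumulated half-sample delays divided out so zero crossings align with
wave peaks. At 500 Hz, QRS boundaries are read at scale 2², P and T waves at
2⁴. The QRS onset (offset) starts from the outermost significant modulus
maximum before (after) the R pair and walks outward until the wavelet
modulus drops below 0.15 of that maximum; the T wave is the strongest
consecutive opposite-signed modulus-maxima pair in a search window from
80 ms after R to min(0.9·RR, 650 ms), its peak the zero crossing between the
pair, its offset the 0.22-threshold crossing after the last maximum. The
edge fractions are larger than the constants quoted for raw-signal
delineators because the wavelet's own smoothing widens each lobe; they were
calibrated so detected boundaries land on the template's 2.5 SD wave edges
(QRS onset bias −3 ms, T offset ±2 ms, mean QT error ~1 ms on clean
signals). Beats with no supra-threshold T pair carry absent T fields; beats
with out-of-order fiducials or windows touching a gap are dropped and
counted.

## RR cleaning and metrics

Cleaning applies the outlier rule first (RR > 2 s or < 300 ms), then the
ectopic rule: each remaining interval is compared with the previous
*retained* interval and flagged at > 20% relative difference. Comparing
against the retained rather than the raw predecessor prevents one outlier
from poisoning its successor. Flags are set, values never mutated.

Metric conventions: SDNN uses the sample (n−1) SD; successive differences
are taken only between adjacent valid intervals; pNNI_50 counts |Δ| strictly
greater than 50 ms; heart rate is 60000/mean(valid RR). Spectral metrics
resample the valid intervals to 4 Hz with a cubic spline and use a Welch
periodogram (Hann window, 120 s segments, 50% overlap — segments shrink for
short windows); total power integrates the PSD below 0.4 Hz and normalized
HF power is the 0.15–0.4 Hz integral divided by total power, following the
convention that ties "relative HF power" to the total below 0.4 Hz. The
Lorenz (Poincaré) indices follow the Toichi convention: with SD1/SD2 the
minor/major axes of the successive-pair scatter, L = 4·SD2, T = 4·SD1,
CSI = L/T and CVI = log₁₀(L·T); this is stated prominently because the
names alone do not pin down a formula. Bazett's QTc = QT/√RR (RR in
seconds) rescales QT to 60 bpm; QTc ≥ 500 ms counts as prolonged.

## Aggregation surfaces

A "day" is a consecutive block from each subject's recording start (no
wall-clock convention is imposed). Days with less than a configurable
minimum of valid ECG coverage (default 4 h for real-scale data; the pipeline
scales it to half the synthetic day length) are dropped with a reason.
Change-from-day-1 is zero on day 1 by construction. Day bins are the
non-overlapping three-day intervals Day 2–4, 5–7, 8–10, 11–13; day 1 is the
baseline and later days are excluded; each subject-day is one observation,
reflecting the large day-to-day variability of ICU physiology.

Event-locked analysis computes each metric in 6-minute windows stepped
3 minutes bi-directionally from session onset and offset. The same tiling
applied across the whole day yields the day's reference mean and SD, and
window values are z-scored against that reference — so session effects are
expressed in units of normal daily variability. Pre/during/post period means
use fully contained windows on the period grid (five windows per 20-minute
period); windows touching a gap (leading/trailing/internal beat gap > 3 s)
are dropped. A zero reference SD makes normalized values absent rather than
infinite.

## Factor analysis

The seven autonomic variables (RMSSD, SDNN, pNNI_50, total power, normalized
HF power, CVI, CSI) are z-scored per subject before factoring, removing
stable between-subject level differences so the factors describe day-to-day
autonomic state. Bartlett's sphericity test gates the analysis (warning, not
error). Extraction is minimum-residual (ULS): the uniquenesses are optimized
by L-BFGS-B to minimize the off-diagonal squared residuals of R − LLᵀ, with
loadings from the reduced-correlation eigenstructure — implemented in the
package because no installed R package provides minres. Rotation is varimax
(`stats::varimax`), scores are regression (Thurstone) estimates, and two
factors are kept per the scree rule (the synthetic structure yields exactly
two eigenvalues > 1).

Factor order and sign are arbitrary, so labels are assigned by loading
pattern, trying both orientations: a factor whose four strongest loadings
are RMSSD, SDNN, pNNI_50 and total power is "Overall HRV"; a factor loading
positively on RMSSD and HF power and negatively on CSI is "Parasympathetic
Activity" (the factor is re-oriented to match). When neither rule fires —
common at small n, or when the generator's correlation structure ranks CVI
above total power — the pipeline falls back to positional assignment.
Recovery tests score Tucker congruence after resolving the
permutation/sign indeterminacy.

## Statistics

Two-group comparisons are gated by Shapiro–Wilk at 0.05 per group (both must
pass): a pooled-variance t-test if normal, otherwise a two-sided,
tie-corrected Mann–Whitney U. Cohen's d with pooled SD is reported
regardless of the chosen test, signed active-minus-sham. Bonferroni
correction multiplies by 6 for the cardiac family (heart rate, QTc, RMSSD,
SDNN, two factors) and 4 for the vitals family. Achieved power for
non-significant results comes from the noncentral t distribution
(df = n₁+n₂−2, ncp = d√(n₁n₂/(n₁+n₂))) at d = 0.5; the required equal-arm
sample size is the smallest n reaching the target power. TOST equivalence
uses two one-sided pooled t-tests against ±margin (5 bpm heart rate, 50 ms
QT, 2 mmHg blood and intracranial pressure), declaring equivalence only when
both reject. The acute model is a REML random-intercept regression of the
per-session post-minus-pre heart-rate change on arm, mRS change and their
interaction, with Satterthwaite p-values and Wald CIs; singular or failed
fits fall back to OLS with a warning. The day-trend model is OLS
`change ~ day × arm`. ANCOVA (`change ~ arm + age`, age as decade midpoints)
checks robustness of arm effects to age.

## Numerical decisions

- All filters are applied forward–backward; the high-pass removes baseline
  (DC) level by design, so amplitude checks use deflections, not absolute
  peak values.
- The wavelet transform is computed via FFT transfer functions with exact
  delay compensation, avoiding per-scale alignment errors of à-trous
  filter-bank implementations.
- The band-amplitude solver refines an analytic start with L-BFGS-B on the
  realization's exact quadratic forms, so target recovery is limited only by
  beat sampling (< 1% at 10 min).
- Degenerate inputs return absent values rather than errors where the
  quantity is genuinely undefined (zero daily SD, SD1 = 0, all-flagged
  series), and errors where the call is a misuse (nonpositive RR, negative
  margin).
- Ties in the refractory rule keep the larger peak; the day-1 baseline is
  defined as the subject's first summarized day.

## Problem sizes used in tests

The test suite runs trial simulations at 2–6 subjects × 3–4 days with 8400 s
days, ECG benchmarks at 1–10 minutes, the mixed-model recovery at 24
subjects × 8 sessions × 200 replicates, and size-control simulations at
1000–2000 replicates; the acceptance script runs the full pipeline at the
default study scale (24 subjects, ~11 days). These sizes were chosen so the
whole suite completes in a few minutes while keeping Monte-Carlo error well
inside the asserted tolerances.

## Known limitations

- The ECG template is stylized: no QRS morphology variants, U waves,
  biphasic T waves, pacemaker spikes or electrode artifacts; delineation
  thresholds are calibrated to the template's Gaussian wave edges.
- The RR model is stationary within a day apart from the injected session
  response; real circadian structure, apnea episodes and arrhythmia runs are
  absent, so spectral metrics see a cleaner world than ICU reality.
- Single-channel analysis only; no 12-lead logic, no arrhythmia
  classification.
- Effect sizes measured on one simulated trial scatter around the configured
  values with the usual sampling error of d at ~100 observations per arm
  (SE ≈ 0.14); the generator's calibration is asserted in expectation across
  seeds, not per run.
- The within-subject correlation of repeated daily changes (shared day-1
  baseline) means pooled-SD effect sizes on subject-days are not independent
  samples — the same caveat the day-as-independent-sample design carries in
  the real analysis.
- Blood-pressure conclusions on real data are confounded by vasopressor
  management; the generator does not model interventions.
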