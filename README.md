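# hrvtrial

Cardiovascular-safety analysis for two-arm auricular vagus nerve stimulation
(taVNS) trials in intensive care, built and validated entirely on synthetic
data with beat-level ground truth.

Transcutaneous auricular VNS is under study as an immunomodulatory treatment
after subarachnoid hemorrhage. Because these patients are acutely vulnerable
to bradycardia, QT prolongation and blood-pressure instability, a safety
analysis must track cardiac and vascular function continuously over the ICU
stay and around each stimulation session. `hrvtrial` implements that whole
chain as reusable R functions:

- **Synthetic trial generator** — two randomized arms, ~11 recording days per
  subject, twice-daily 20-minute sessions, configurable standardized arm
  effects on each metric's change-from-day-1, RR-interval series with
  controlled LF/HF spectral structure, template ECG with analytically known
  fiducials, 1 Hz vitals, treatment-event traces, monitoring gaps, injected
  ectopic/outlier beats — all reproducible from one seed.
- **ECG processing** — zero-phase 0.5 Hz fifth-order Butterworth high-pass and
  60 Hz notch, gradient-based R-peak detection with a 200 ms refractory
  period, and quadratic-spline wavelet (modulus-maxima) delineation of P, QRS
  and T waves.
- **RR metrics** — cleaning (outliers > 2 s or < 300 ms; ectopic beats with
  > 20% jump from the previous retained interval), heart rate, RMSSD, SDNN,
  pNNI_50, total power (< 0.4 Hz), normalized high-frequency power
  (0.15–0.4 Hz), Lorenz-plot CVI/CSI, Bazett QTc = QT/√RR, and the
  prolonged-QTc (≥ 500 ms) fraction.
- **Aggregation** — per-day summaries and change-from-day-1, three-day bins
  (Day 2–4 … 11–13), and event-locked 6-minute sliding windows (3-minute
  step) normalized to a same-day sliding-window reference, with
  pre/during/post session deltas.
- **Factor analysis** — minres extraction + varimax rotation of the
  seven-metric autonomic set, with rule-based labeling of the "Overall HRV"
  and "Parasympathetic Activity" factors.
- **Statistics** — Shapiro–Wilk-gated t / Mann–Whitney comparisons with
  Cohen's d and Bonferroni correction, Wilcoxon signed-rank vs zero, TOST
  equivalence (margins 5 bpm / 50 ms / 2 mmHg), noncentral-t power and sample
  size, day×treatment interaction regression, random-intercept mixed model of
  acute heart-rate response vs clinical outcome (mRS change), age ANCOVA, and
  Pearson correlation.

## Worked example

```r
library(hrvtrial)

# power the analysis plan is built around: two-sample t-test, d = 0.5
power_two_sample_t(94, 95, d = 0.5, alpha = 0.05)
#> [1] 0.9277472
required_n(power = 0.80, d = 0.5)
#> [1] 64

# a synthetic day: RR series hitting SDNN 50 ms / RMSSD 30 ms
g <- generate_rr_series(rr_gen_params(mean_rr = 800, sdnn_target = 50,
                                      rmssd_target = 30, seed = 1), 600)
m <- hrv_metrics(g$rr, qt = 400 * sqrt(g$rr$rr / 1000))
round(c(hr = m$hr, rmssd = m$rmssd, sdnn = m$sdnn, qtc = m$qtc_mean), 2)
#>    hr rmssd  sdnn   qtc
#>    75    30    50   400

# render it as ECG, detect and delineate, measure QT
syn <- synthesize_ecg(g$rr, qt_fun = function(rr_s) 400 * sqrt(rr_s))
filt <- ecg_preprocess(syn$ecg)
fid <- delineate(filt, detect_r_peaks(filt))
round(mean(fid$qt_ms, na.rm = TRUE), 1)   # truth is 400*sqrt(RR); 357.6 here
#> [1] 358.6
```

`run_pipeline(default_config(seed = 1))` runs the full chain on a 24-subject
synthetic trial (11 taVNS / 13 sham, ~11 days each) and returns the daily and
binned comparison tables, the factor model, event-locked session deltas, the
equivalence/power report and the mixed-model coefficients; with `out_dir` it
also writes CSV tables, a JSON stats bundle and a run log.

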