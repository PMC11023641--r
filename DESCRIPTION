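Package: hrvtrial
Title: Cardiovascular Safety Analysis of Auricular Vagus Nerve Stimulation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for the cardiovascular safety of
    transcutaneous auricular vagus nerve stimulation (taVNS) in intensive-care
    trials: synthetic two-arm trial generation with beat-level ground truth,
    ECG filtering and wavelet delineation, RR-interval cleaning, time- and
    frequency-domain heart rate variability, Bazett QTc, daily and
    event-locked aggregation, exploratory factor analysis of autonomic
    metrics, and the statistical layer (normality-gated group comparisons,
    TOST equivalence, noncentral-t power, interaction regression, linear
    mixed models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
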