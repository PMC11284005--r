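Package: vtscreen
Title: Ventricular Tachycardia Screening from Sinus-Rhythm Holter ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies ventricular-tachycardia (VT) patients from the
    sinus-rhythm portions of long-term Holter ECG recordings. Implements
    quality-gated 30-minute windowing with a beat-agreement signal quality
    index (bsqi), dual QRS detection, rule-based beat classification,
    heart-rate-variability (including heart-rate-fragmentation) and ECG
    morphology feature engineering, minimum-redundancy maximum-relevance
    feature selection with gradient-boosted trees under patient-disjoint
    nested cross-validation, and per-patient median probability aggregation.
    Ships a synthetic Holter cohort generator with class-dependent ectopy
    burden, RR fragmentation and noise episodes, providing full ground truth
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    xgboost,
    ranger,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
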