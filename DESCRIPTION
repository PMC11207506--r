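Package: qappg
Title: Quality-Aware Signal Processing for Wrist PPG Heart-Rate Monitoring
Version: 0.1.0
Authors@R:
    person("Quality-Aware PPG", "Maintainers", email = "qappg@example.org",
           role = c("aut", "cre"))
Description: Energy-aware processing of wrist photoplethysmography (PPG) for
    long-term heart-rate monitoring. Each 10 s PPG segment is scored with 14
    signal-quality indices (SQIs); a cascade of energy-ordered boosted binary
    classifiers then routes the segment to one of up to three processing
    algorithms drawn from an energy-budgeted, Hamming-distance-diversified
    portfolio (bypass, Butterworth filters, cubic-spline baseline removal,
    wavelet filtering, SVD of the time-frequency distribution, empirical mode
    decomposition, singular spectrum analysis), or discards it. Heart rate is
    estimated from the spectral peak in the cardiac band. Includes one-for-all
    and quality-gating baseline frameworks with per-segment energy accounting,
    and a seeded synthetic wrist-PPG generator (clean pulse waveforms,
    baseline wander, graded typing-burst artifacts) so the full pipeline is
    testable without access to proprietary recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
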