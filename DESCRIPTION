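Package: afdetect
Title: Automated Atrial Fibrillation Detection in Continuous ICU Telemetry ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ensemble detector for atrial fibrillation (AF) in long continuous
    telemetry electrocardiograms such as those recorded in intensive care units.
    Records are divided into 2-minute segments that are gated by a rule-based
    signal-quality index, QRS complexes are detected on a variable-frequency
    complex demodulation (VFCDM) reconstruction of the QRS band, RR-interval
    sample entropy screens segments for possible AF, and premature atrial and
    ventricular beats are discriminated from AF using Poincare plots of
    heart-rate differences together with P-wave evidence extracted by empirical
    mode decomposition. Patient-level AF episodes require three consecutive AF
    segments. Includes two published RR-interval comparator detectors, an
    evaluation module (contingency tables, exact binomial confidence intervals,
    paired accuracy tests, onset-latency summaries), and a synthetic multi-lead
    ECG generator with ground-truth annotations for sinus rhythm, AF, ectopy and
    ICU noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
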