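Package: ecgflow
Title: ECG Filtering, QRS Detection, and Heart-Rhythm Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for single-lead electrocardiogram (ECG) analysis: synthetic
    ECG generation with known ground truth, reading WFDB (formats 212 and 16)
    and plain CSV records, baseline-wander and power-line filtering with FIR
    and Butterworth IIR stages, minimax reduction of high-order IIR transfer
    functions to low-order all-nonnegative-coefficient filters,
    Hilbert-envelope and Pan-Tompkins QRS detection, time-domain and Poincare
    heart-rate-variability summaries, and rule-based regular/irregular rhythm
    classification with confusion-count evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
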