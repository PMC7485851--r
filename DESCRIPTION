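Package: aurea
Title: Automated Unsupervised Respiratory Event Analysis for Dual-Belt
    RIP Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sample-by-sample classification of infant breathing patterns
    from dual-belt respiratory inductance plethysmography (RIP) recordings.
    Implements the AUREA method: six sliding-window signal metrics
    (log normalized variance, nonperiodic power, synchronous and
    asynchronous breathing power), instantaneous respiratory frequency and
    thoracoabdominal phase, a cascade of four binary k-means detectors with
    unbalanced-data boundary adjustment, an evaluation framework (confusion
    matrix, accuracy, precision, recall, F-score, event fragmentation and
    pattern matching), and a synthetic RIP record simulator with
    ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
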