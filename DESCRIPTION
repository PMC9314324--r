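Package: qrseg
Title: Single-Pass QRS Detection and Beat Classification for Holter ECG
Version: 0.1.0
Authors@R:
    person("MDT", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and classifies QRS complexes (normal, premature atrial
    contraction, premature ventricular contraction) in single-lead Holter ECG
    in one inference step. A five-block 1D residual network followed by a
    gated recurrent layer produces a per-sample four-channel segmentation
    mask at 100 Hz; deterministic post-processing (argmax, segment centers,
    close-peak suppression) converts the mask into time-stamped beat
    annotations. Includes WFDB and CSV/JSON record readers, a synthetic
    Holter ECG simulator with movement-noise artifacts for training and
    evaluation without external data, the full training recipe (AdamW,
    gradient clipping, random inversion and cropping, weighted
    oversampling), and tolerance-matched F1 evaluation of detection and
    classification performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
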