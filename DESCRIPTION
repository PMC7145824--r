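Package: ecgdx
Title: Automatic 12-Lead ECG Abnormality Classification with a 1D Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying six rhythm and conduction
    abnormalities (first-degree AV block, right and left bundle branch block,
    sinus bradycardia, atrial fibrillation, sinus tachycardia) in short
    12-lead electrocardiograms. Provides a seeded synthetic 12-lead ECG
    generator with ground-truth labels and measurements; HDF5/CSV dataset
    container I/O and the standard preprocessing (resampling to 400 Hz,
    zero-padding to 4096 samples); an RR-interval measurement oracle (R-peak
    detection, heart rate, SDNN, PR/QRS estimation); a weak-supervision label
    construction engine (n-gram text features, lazy associative
    classification, rule-based disambiguation, and measurement-based
    harmonization of expert and automatic annotations); a unidimensional
    pre-activation residual network with training loop (Adam, plateau
    learning-rate schedule, best-on-validation checkpointing) implemented on
    RcppArmadillo kernels; and a multi-label evaluation suite
    (precision-recall curves, F1-maximizing thresholds, micro average
    precision, bootstrap confidence intervals, McNemar test, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    rhdf5,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
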