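Package: lonnrec
Title: Interpretable Logic-Operator Neural Networks for Therapy
    Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Continuous-valued (nilpotent) logic primitives built on the
    squashing activation function, feed-forward logic-operator neural
    networks (LONN) whose hidden logic-gate layers are frozen perceptrons,
    mini-batch ADAM training, a parametric heart-failure cohort fixture
    generator, a sequential-regression synthetic-cohort generator with
    frequency-distribution distance diagnostics, a dual-model (full vs
    positive-outcome) therapy recommender with binary confidence, and the
    evaluation protocols (training error, therapy classification metrics,
    therapy-time RMS, beta sweeps, topology comparison, first-layer
    parameter-hierarchy ranking).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
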