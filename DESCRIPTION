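Package: nsclcstager
Title: Assisted Staging and Treatment Decision Support for Non-Small
    Cell Lung Cancer from Medical-Record Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating a text-based assisted
    diagnosis pipeline for non-small cell lung cancer (NSCLC) staging.
    Patient medical records (tumor markers, demographics, symptoms) are
    rendered as token sequences, embedded with a skip-gram word-vector
    model, and classified with a small convolutional neural network with
    multi-scale kernels and 1-max pooling. Staging uses a One-vs-Rest
    decomposition with a co-occurrence-based transfer-learning source
    selection rule and a dynamic-sampling iterative training algorithm
    that rebalances severely imbalanced stage classes. Model confidences
    map to a clinical decision value, a stage, a treatment
    recommendation, and a treatment-efficacy assessment. A seeded
    synthetic cohort generator makes the whole pipeline testable without
    access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
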