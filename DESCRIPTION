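Package: cogstage
Title: Staging Cognitive Impairment from Neuropsychological Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for classifying stages of cognitive decline
    (cognitively normal, subjective memory concern, early and late mild
    cognitive impairment, Alzheimer's disease) from tabular
    neuropsychological assessment data in the ADNIMERGE dialect. Implements
    ordered inclusion-criteria filtering and nominal encoding, thirteen
    pairwise comparison datasets across two diagnostic phases,
    boosting-guided synthetic augmentation for class balance, recursive
    feature elimination with a joint AIC and cross-validated accuracy
    stopping rule, an exhaustive AIC-minimising subset refiner, a
    five-member hard-voting classifier ensemble under stratified 10-fold
    cross-validation, and confusion-matrix metrics with explicit
    undefined-value semantics. A synthetic cohort generator emulates the
    ADNIMERGE schema so the whole pipeline is exercisable without
    access-controlled data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    nnet,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
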