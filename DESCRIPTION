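Package: idscreen
Title: Craniofacial and Phonetic Feature Analysis for Intellectual Disability Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Landmark-based screening analysis for intellectual disability from
    interview videos. Reads OpenFace-2.0-style per-frame facial records (68 3D
    landmarks, head pose, gaze, tracker confidence), applies frame-quality
    filters, and computes 30 named geometric features of the facial phenotype.
    The first 11 measurements are standardized against a normative reference and
    summarized by the craniofacial variability index (CVI), the standard
    deviation of the measurement z-scores. Subject-level phonetic feature
    matrices following the INTERSPEECH 2010 paralinguistic schema (1582
    features) are reduced to 38 dimensions with radial-basis-function kernel
    principal component analysis implemented from first principles. Random
    Forest, discrete AdaBoost and Gaussian Naive Bayes classifiers are evaluated
    on three feature sets with stratified cross-validation, including a
    better-than-chance comparison. A fully seeded synthetic-cohort generator
    (landmark frame streams and phonetic matrices with configurable group
    effects) makes every stage testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    withr,
    randomForest,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite,
    optparse
Config/testthat/edition: 3
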