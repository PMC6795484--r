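Package: odcert
Title: Drug Overdose Death Classification from Death-Certificate Free Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies drug overdose deaths from the free-text cause-of-death
    sections of death certificates, ahead of ICD-10 underlying-cause coding.
    Implements binary word/bigram/trigram bag-of-words featureization of
    certifier text, linear support vector machine, random forest and
    multilayer perceptron classifiers tuned by F-score under repeated
    stratified cross-validation with iterative grid refinement, a rule-based
    keyword baseline, evaluation statistics (PPV, sensitivity, specificity,
    F-score, two-proportion z-tests), and a synthetic certificate generator
    for testing the pipeline without access to restricted vital-statistics
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    ranger,
    nnet,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
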