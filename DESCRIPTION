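Package: qcla
Title: Question-Based Computational Language Assessment of Emotional States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for question-based computational language assessment (QCLA):
    building latent semantic analysis (LSA) spaces from descriptive-word
    response corpora (co-occurrence counting, log(1+x) transform, truncated
    SVD, unit-norm word vectors), embedding five-word responses, classifying
    four emotional states (harmony, satisfaction, depression, anxiety) with
    multinomial logistic regression under narrative-grouped nested
    cross-validation with semantic-dimension selection, predicting rating-scale
    totals (PHQ-9, GAD-7, SWLS, HILS) from word responses by cross-validated
    linear regression, scoring and alexithymia-stratifying the PAQ, a full
    evaluation layer (confusion matrices, metric panels, chi-squared and phi
    effect sizes, t- and F-tests, Pearson correlations, Bonferroni correction),
    ranked word-cloud tables with permutation significance screening, and a
    synthetic two-phase study generator so the whole pipeline is testable
    without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    nnet,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
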