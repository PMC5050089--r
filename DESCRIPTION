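Package: dietcalib
Title: Intervention Effects on Error-Prone Dietary Outcomes with Biomarker
    Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimation of a two-arm intervention effect when the outcome
    (dietary intake) is measured by biased self-report in all participants
    and by replicated unbiased biomarkers in a calibration sub-study.
    Implements method-of-moments estimators of the effect and of the
    self-report error model under differential and non-differential error,
    their inverse-variance-weighted (Buonaccorsi) combination with
    estimating-equation sandwich variances, full maximum-likelihood
    estimation of the joint multivariate-normal measurement model with
    model-based and robust variances and likelihood-ratio tests, and a
    Monte-Carlo engine for bias, coverage and relative-efficiency studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
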