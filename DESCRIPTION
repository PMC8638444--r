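Package: pvsignal
Title: Adaptive Lasso and Related Signal Detection Methods for Pharmacovigilance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated drug-safety signal detection from spontaneous report
    databases, treating detection as variable selection in a sparse logistic
    regression of one adverse event on all drug-exposure indicators. Implements
    lasso detectors with cross-validation, BIC or permutation-based selection of
    the regularization parameter, the class-imbalanced subsampling lasso (CISL),
    five adaptive-lasso detectors (including weights derived from a BIC-selected
    lasso and from CISL), high-dimensional propensity-score detectors
    (adjustment, IPTW, truncated IPTW, matching weights) and a reporting Fisher
    exact test baseline, together with a synthetic-data engine emulating sparse
    spontaneous-report exposure matrices and an FDR/sensitivity evaluation
    harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    methods,
    sandwich,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
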