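Package: ossubtype
Title: Branch-Marker Discovery and Consensus Subtyping of Osteosarcoma
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving differentiation-branch marker panels from
    clustered single-cell osteosarcoma expression data and using them to
    subtype bulk tumor cohorts. Implements single-cell quality control,
    log-normalization, variable-gene selection and clustering; one-vs-rest
    Wilcoxon marker statistics with cross-cluster exclusivity filtering;
    resampling consensus clustering with PAC-based selection of the number
    of subtypes; single-sample subtype assignment by panel-score or
    strongest-marker argmax rules (including immunohistochemistry score
    tables); and Kaplan-Meier / log-rank survival comparison of subtypes.
    A negative-binomial synthetic-data generator emulating a stem-cell-rooted
    three-branch tumor structure makes the whole pipeline testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    MASS,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    withr
Config/testthat/edition: 3
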