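Package: pedsep
Title: Computable 24-Hour Pediatric Sepsis Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation and bedside application of computable 24-hour pediatric
    sepsis phenotypes. Provides a calibrated synthetic patient-day cohort
    generator, a rule engine for empirical multiple-organ-failure phenotypes
    (TAMOF, MAS, IPMOF, SMOF, NPMOF) and the organ failure index, variable
    screening by missingness and correlation, consensus k-means clustering with
    CDF delta-area model selection, nearest-centroid phenotype assignment for
    individual patients, phenotype association statistics, and penalized
    screening of heterogeneous treatment interactions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
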