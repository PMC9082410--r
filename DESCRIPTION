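Package: healthineq
Title: Concentration-Index Analysis of Consumption-Related Health-Education Inequality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring socioeconomic inequality in health-education
    outcomes from household survey microdata. Builds a PCA-weighted household
    consumption composite with reliability diagnostics, fits coordinate-descent
    Lasso regressions with cross-validated penalty selection and
    post-double-selection inference for the consumption effect, and estimates
    weighted concentration indices, concentration curves, horizontal inequity
    via need-factor standardization, and the Wagstaff decomposition of the
    concentration index into per-factor elasticities and contributions.
    Includes a seeded Gaussian-copula survey simulator with a known linear
    data-generating process so every stage can be validated against ground
    truth, and a config-driven pipeline that writes tabular, JSON and graphical
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    sandwich,
    ggplot2
Suggests:
    glmnet,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
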