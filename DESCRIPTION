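Package: isonich
Title: Isotopic Niche, Diet Mixing and Trait-Change Partitioning for
    Plankton Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for stable-isotope trophic ecology of
    zooplankton time series: Bayesian diet-source mixing models with
    a-priori Monte Carlo mixing-polygon screening, Layman community-wide
    metrics and standard ellipse areas (including Bayesian posterior
    estimation and ellipse overlap), Price-equation partitioning of
    community trait change into taxa sorting, intrataxonomic variation and
    turnover, environment-community linkage (PERMANOVA, collinearity and
    VIF pruning, Spearman linkage) and partial least squares path
    modeling. Includes a synthetic reservoir data generator with ground
    truth for recovery tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
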