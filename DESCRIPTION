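Package: reefvuln
Title: Bayesian Hierarchical Spatial Models for Coral Bleaching Vulnerability Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects coral occurrence, percent cover and bleaching
    probabilities over a coastal grid with Bayesian hierarchical spatial
    models (Bernoulli-logit occurrence and conditional lognormal abundance
    with a Matern Gaussian-field random effect), screens environmental
    covariates by Pearson correlation and generalized variance inflation
    factors, selects covariates forward by WAIC and the conditional
    predictive ordinate, projects fitted models under climate-scenario
    covariate shifts, and combines the three projections into a
    bleaching-vulnerability surface with quartile hotspot classification.
    Includes a seeded synthetic-data generator emulating coastal
    environmental raster stacks and reef survey observations so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
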