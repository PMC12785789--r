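Package: ecikinetics
Title: Electrochemical Color Index Kinetics of Barrel-Aged Agave Distillates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for monitoring the early maturation of agave distillates
    in toasted oak barrels. Computes the Electrochemical Color Index (ECI)
    from differential-pulse voltammograms, fits a bi-exponential
    extraction/adsorption kinetic model to ECI time series by variable
    projection with multi-start, segments the characteristic early-maturation
    kinetic phases with a piecewise-linear changepoint search, quantifies
    wood-stave surface texture with gray-level co-occurrence matrices
    (contrast, entropy, homogeneity, energy, correlation) and local
    standard-deviation heterogeneity maps, and relates structural descriptors
    to kinetic parameters through standardized PCA, Spearman rank correlation
    and one-way ANOVA. Includes seeded simulators for voltammograms, ECI
    kinetics and stave surface images so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
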