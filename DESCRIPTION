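Package: forestAGB
Title: Forest Aboveground Biomass Mapping, Allometric Uncertainty, and
    Inventory Inter-Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating plot-based forest inventories with
    wall-to-wall biomass maps derived from airborne laser scanning.
    Implements tree-level aboveground biomass prediction under three
    allometric model families (generalized ln-ln group equations,
    volume-based component-ratio chains, and species-specific equations
    with a group-level fallback), simulation-based propagation of
    allometric model error to plot-level 95% confidence intervals,
    Bayesian spatial Gaussian-process regression with exponential
    covariance for per-pixel biomass prediction intervals, plot-to-pixel
    agreement statistics (OLS agreement, RMSE, two-sample
    Kolmogorov-Smirnov distance, confidence-interval overlap), and
    design-based versus pixel-based county-scale totals including the
    forest/nonforest censoring decomposition. A synthetic-landscape
    generator reproduces the statistical structure the analysis assumes
    (clustered four-subplot inventory plots, Weibull diameter
    distributions, condition censoring, noisy monotone canopy metrics) so
    the full pipeline is testable without confidential plot coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
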