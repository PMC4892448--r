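Package: nestpp
Title: Endogenous and Exogenous Drivers of Clustered Nest Point Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial point-process analysis for annual censuses of sessile
    organisms (arboreal ant nests on shade trees) that disentangles
    endogenous, density-dependent pattern formation from exogenous habitat
    drivers. Provides pair-correlation, K and L summary statistics with
    translation edge correction and habitat-conditioned Monte Carlo
    envelopes; inhomogeneous Poisson process models fitted by Berman-Turner
    quadrature with AIC comparison; inhomogeneous Thomas cluster processes
    fitted by two-step minimum contrast on the intensity-weighted K with
    clustering-adjusted coefficient covariances; parametric bootstrap
    confidence intervals, maximum-absolute-deviation goodness-of-fit tests,
    and break-even / Allee threshold analysis of density dependence; plus a
    synthetic-data module that generates tree censuses, terrain rasters and
    budding nest dynamics with the statistical structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
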