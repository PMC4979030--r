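Package: clustercorr
Title: Bias and Identifiability of Correlation-Based Cluster Estimators for
    Spatial Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the bias and identifiability of
    correlation-based estimators of spatial cluster parameters, as used in
    single-molecule localization microscopy (PALM/STORM) cluster analysis.
    Provides closed-form Ripley K, Besag L(r)-r and pair correlation functions
    for Neyman-Scott cluster processes (Thomas/Gaussian, Matern/disk, Cauchy,
    variance-Gamma) and an Ornstein-Zernike Ising form; a seedable Neyman-Scott
    simulator with optional random monomer background; translation-corrected
    empirical K, L and kernel pair-correlation estimators; the theory of the
    radius of maximal aggregation (its nonlinear dependence on cluster density
    and size, and model-specific lower bounds); a variance-normalized K
    statistic; and least-squares fitting of the exponential pair-correlation
    approximation together with the scaling laws relating its parameters to
    the true cluster model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
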