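Package: metaplast
Title: Phenotypic Plasticity and Stability Analysis of Multi-Environment
    Metabolite Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-environment metabolomic profiling
    of crop varieties: variance partitioning of Bray-Curtis dissimilarities
    by permutational multivariate analysis of variance, a principal-component
    triangle-area metric of varietal variability, an amplitude-based
    phenotypic-plasticity screen with contingency-style expected amplitudes
    and standardized Pearson residuals, and classical stability models
    (Finlay-Wilkinson joint regression, Wricke ecovalence, AMMI
    decomposition with biplot coordinates). Includes a synthetic-data
    generator emulating crossed variety x environment x block designs with
    known variance components, interaction structure and environmental
    sensitivities, for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    vegan,
    randomForest,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
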