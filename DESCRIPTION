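Package: cgmi
Title: Composite Growth Monitoring Indices from UAV Multispectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds comprehensive growth monitoring indices (CGMI) for plot-level
    plant stands from four field indicators (SPAD, plant height, leaf area index,
    aboveground biomass) using equal and coefficient-of-variation weighting,
    computes a twelve-index vegetation-index library from five-band canopy
    reflectance, screens indices by Pearson correlation, and inverts the
    composite index with a suite of regressors (multiple linear regression,
    partial least squares, support vector regression, random forest, radial
    basis function network, back-propagation neural network) including a
    whale-optimization-algorithm-initialised back-propagation network. Includes
    a synthetic plot-table generator with a latent plot-vigor factor so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    optparse
Config/testthat/edition: 3
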