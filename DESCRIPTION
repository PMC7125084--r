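Package: rhizocohere
Title: Root-Soil Cohesion, Uprooting Mechanics and Erosion-Reduction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for measuring how fine root traits (root
    hairs in particular) bind plants to their substrate and protect soil from
    concentrated-flow erosion. Implements the centrifuge force balance behind
    seedling-gel detachment assays and the resulting detachment survival
    curves; peak-force, energy and force-drop extraction from uprooting
    force-displacement traces; empirical exponential/plateau erosion-reduction
    models in root length density with Monte-Carlo confidence bands;
    back-calculation of soil cohesion from measured detachment rates through
    the EUROSEM flow-detachment efficiency; and a mechanistic Mohr-Coulomb
    erosion model with a saturating root-hair cohesion-enhancement function
    calibrated against observed erosion-reduction curves. A set of synthetic
    data generators reproduces the statistical structure of each assay so the
    full pipeline is testable without the original measurements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
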