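Package: gnplem
Title: Gold Nanoparticle Radiosensitization Modelling with the Local Effect Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the radiosensitization effect of intracellular gold
    nanoparticles (GNPs) under megavoltage photon irradiation. Builds
    calibrated radial excess-dose kernels around single GNPs, samples GNP
    positions in an elliptical cell model under uniform-cytoplasm,
    perinuclear and intravesicular distribution scenarios, superposes
    per-GNP radial doses onto nucleus integration points, and converts the
    heterogeneous nuclear dose into clonogenic survival with a
    linear-quadratic local effect model (GNP-LEM). Also provides the
    companion assay statistics: clonogenic plating efficiency and survival
    fractions, per-cell GNP uptake from gold mass, DNA double-strand-break
    focus densities per nuclear area, Bliss-independence combination
    analysis, Poisson tumor control probability over fractionated
    schedules, and seeded synthetic-data generators that emulate the
    statistical structure of each assay so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
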