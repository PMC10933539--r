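Package: tlscarbon
Title: Tree Structure, Biomass and Carbon from Terrestrial Laser Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline from per-tree terrestrial laser scanning (TLS) point
    clouds to structural metrics, aboveground biomass, carbon and annual
    growth rates for open-grown conifers. Reads PLY/XYZ/LAS point clouds,
    derives height, stem diameters (DBH, DTB, functional DBH), convex-hull
    crown volume and a slice-stack woody volume with repeat-fit uncertainty,
    converts volume to biomass and carbon with configurable wood density and
    carbon fraction, evaluates published allometric models and fits new
    power-law allometries by arithmetic-space nonlinear least squares with
    parametric bootstrap uncertainty. Includes a synthetic tree point-cloud
    generator with closed-form ground truth so every estimator is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
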