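Package: cyanoflux
Title: Constraint-Based Analysis of Cyanobacterial Phototrophic Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scenario-driven flux balance analysis (FBA) for cyanobacterial
    metabolism. Provides a tidy data model for constraint-based metabolic
    networks with SBML input/output and elemental/charge balance checking, a
    linear-programming core (FBA, flux variability analysis, flux-ratio
    coupling constraints, forced-flux scans), named analysis scenarios for
    phototrophic growth, dark metabolism, TCA-cycle closure variants,
    photorespiration and glyoxylate-shunt tests, a diurnal dynamic FBA with a
    time-varying biomass objective and glycogen storage dynamics, and a
    transcript-rhythm pipeline (spectral power at 1/day, permutation p-values,
    least-oscillating-set selection, loess normalization, Fourier phase).
    Ships a mass-balanced synthetic cyanobacterial core network generator with
    pathway toggles for fully offline, reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
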