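Package: gridrt
Title: Monte Carlo Dosimetry for Grid (Spatially Fractionated) Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale Monte Carlo photon/electron transport engine and
    analysis pipeline for megavoltage grid therapy (spatially fractionated
    radiotherapy, SFRT). Simulates open and grid-collimated 6 MV fields in a
    water phantom with primary/scatter tagging, scores dose meshes and
    track-length fluence spectra, and computes the standard dosimetric
    quantities of SFRT commissioning: percentage depth dose and the depth of
    dose maximum, output factors, the TPR20/10 beam-quality index, spectrum
    average energies, percentage depth fluence, the valley-to-peak spatial
    fraction, and primary/scatter dose decomposition. Includes a 1D gamma-index
    module for dose-curve comparison and a parametric 6 MV source model with a
    tuning loop against reference depth-dose and profile curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
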