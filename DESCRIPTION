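Package: boltzms
Title: Thermodynamic Prediction of Peptide Fragment-Ion Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts relative y- and b-ion intensities in tandem mass
    spectra of doubly charged tryptic peptides from Boltzmann populations
    of backbone-protonated precursor isomers. Provides conformer-ensemble
    containers with energy-window filtering and Kabsch-RMSD duplicate
    removal, harmonic-oscillator/rigid-rotor/ideal-gas thermochemical
    corrections, four energy variants for the Boltzmann weighting,
    fragment-ion m/z computation, peak-list annotation, and log-relative-
    error scoring against measured spectra, together with seeded synthetic
    fixtures for end-to-end testing without quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
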