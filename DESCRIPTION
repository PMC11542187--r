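Package: cagesense
Title: Conceptual-DFT Descriptors and Sensor-Response Modelling for
    Nanocage Gas Adsorption Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Post-processing pipeline for quantum-chemistry screening of
    fullerene-like X12Y12 nanocage gas sensors.  Computes frontier-orbital
    reactivity descriptors (chemical potential, hardness, electrophilicity,
    work function), cohesion and counterpoise-corrected adsorption
    energetics, band-gap conductivity and Richardson-Dushman thermionic
    response, transition-state-theory recovery times, conductometric and
    work-function selectivity coefficients, and Gaussian-broadened UV-vis
    absorption spectra from tabulated electronic-structure results.  Ships
    a curated reference dataset of Cu-modified B12N12 and Al12N12 nanocages
    probed with cadaverine and interfering gases, and a synthetic campaign
    generator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
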