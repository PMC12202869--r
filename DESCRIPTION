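Package: ventlight
Title: Photon Budgets for Mineral-Mediated Visible Light at Deep-Sea
    Hydrothermal Vents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for the hypothesis that sulfide minerals
    at deep-sea hydrothermal vents up-convert geothermal infrared radiation
    into biologically usable visible light by second harmonic generation
    (SHG).  Provides Planck blackbody photon radiometry and band-integrated
    photon fluxes; SHG phenomenology (half-wavelength mapping, quadratic
    power-law fitting, loss-corrected conversion efficiency, pressure
    enhancement, multiplicative photon budgets); multi-Gaussian
    decomposition of cyanobacterial fluorescence spectra with substrate
    controls; emission-pigment overlap scoring; photosynthesis-apparatus
    gene completeness scoring from read-gene alignment tables; and seeded
    synthetic-data generators so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    vegan
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
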