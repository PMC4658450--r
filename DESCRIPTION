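Package: domlink
Title: Linking Dissolved Organic Matter Optical Properties to Molecular Formulae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for associating the optical properties of dissolved organic
    matter (CDOM absorbance indices, fluorescence indices, and EEM-PARAFAC
    components) with ultrahigh-resolution mass-spectrometry molecular formulae.
    Implements elemental-formula arithmetic (monoisotopic mass, modified
    aromaticity index, stoichiometric compound classes), absorbance metrics
    (Napierian coefficients, SUVA254, spectral slopes and their ratio),
    excitation-emission matrix hygiene and scalar indices (FI, freshness, HIX),
    a nonnegative trilinear PARAFAC decomposition with split-half validation,
    CHNOSP molecular-formula assignment with dynamic-range (SDL) intensity
    standardization, per-formula Spearman rank screening against optical
    drivers, and a fully specified synthetic-cohort generator with a
    machine-readable ground-truth manifest so every stage is verifiable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
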