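Package: meisoquant
Title: Morphometry, Co-Localisation and Contact Mechanics for Epidermal Membrane Organelles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantification pipeline for meisosomes, the stacked apical
    plasma-membrane folds of the C. elegans epidermis. Implements
    background-normalised blob segmentation of fluorescence micrographs with
    per-object morphometrics (area, Feret's diameter, object density),
    object-based two-channel co-localisation by centroid containment,
    AFM force-curve processing (baseline zeroing, contact-point detection,
    cantilever-bending subtraction) with Hertz spherical-indenter fits of
    Young's modulus, and a normality/variance-screened two-group test
    selection rule. A synthetic-data module generates ground-truth-labelled
    reticulated and fragmented scenes, paired co-localisation channels and
    Hertz force curves so every stage is testable without micrographs or an
    instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    tiff,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
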