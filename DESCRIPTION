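Package: smlmclassify
Title: Pattern Classification for Single-Molecule Localization Microscopy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless, scriptable classification of nanoscale patterns (DNA-origami
    digits, grids and similar structures) in single-molecule localization
    microscopy (SMLM) data. Picked regions of a localization table are rendered
    into oversampled 2D-histogram grayscale images, a small multilayer
    perceptron (up to three hidden layers, trained from scratch with
    backpropagation) is fitted on rotation-augmented training images, and new
    datasets are classified pick-by-pick with per-class export of localizations
    in the standard SMLM HDF5+YAML dialect. A built-in DNA-PAINT simulator
    generates ground-truth datasets (digit and 20-nm-grid binding-site patterns,
    Poisson event counts, Gaussian localization noise, partial labeling, uniform
    background) so the whole pipeline is testable end to end without microscope
    data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nnet,
    jsonlite,
    optparse
SystemRequirements: HDF5 C library (libhdf5)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
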