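Package: rspaquant
Title: Quantification of Single-Cell Prostaglandin E2 Secretion from
    Radial PKA Activation Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the amount of prostaglandin E2 (PGE2)
    discharged by a single cell from ratiometric FRET time-lapse imaging
    of PKA activity in surrounding reporter cells. Provides a finite
    difference solver for the axisymmetric diffusion of an instantaneous
    point release into the medium above a dish, Hill dose-response
    calibration of the biosensor and inversion of a fractional ratio
    threshold into an iso-concentration contour, detection and
    nearest-neighbour tracking of radial PKA activation events in
    normalized ratio stacks, calcium transient analysis (F/F0 with a
    sliding-minimum baseline), a ground-truthed synthetic scene generator
    for end-to-end validation, and conversion of observed event radii
    into femtomoles secreted per calcium transient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
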