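Package: phenovid
Title: Low-Cost 3D Phenotyping of Leafy Vegetables from Smartphone Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for measuring three-dimensional phenotypes of
    rosette-forming leafy vegetables (plant height, leaf number, leaf length,
    leaf angle) from smartphone video recordings. Sharp, crop-containing key
    frames are selected from a frame sequence by Laplacian blur gating,
    excess-green-minus-excess-red (ExGR) vegetation-index saliency and
    scale-invariant feature matching; an externally reconstructed dense point
    cloud is then ground-aligned with RANSAC, simplified and de-noised; a
    skeleton is extracted by height-slice clustering with branch pruning and
    cubic B-spline smoothing; and traits are reported in real-world units via
    calibration cubes of known edge length. A seeded synthetic-scene generator
    provides ground-truth fixtures for every stage.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    splines,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
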