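Package: cryopickr
Title: Fully Automated Particle Picking for Cryo-EM Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-component pipeline for fully automated single-particle
    picking in cryo-electron microscopy micrographs. Component one builds a
    labeled training set without manual annotation: micrographs are enhanced
    by a seven-step preprocessing chain, segmented into binary particle masks
    by intensity-based and superpixel k-means clustering, and candidate
    particles are accepted or rejected by geometric rules (circular Hough
    transform fits, circularity, Feret diameters, area statistics). Component
    two trains a convolutional neural network on the generated crops and picks
    particles in new micrographs by automatic scaling, sliding-window scoring,
    score-map cleaning and non-maximum suppression. Includes a synthetic
    micrograph simulator with known ground truth, readers and writers for MRC,
    PNG/TIFF, EMAN box and RELION coordinate STAR formats, and detection
    evaluation metrics with precision-recall curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
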