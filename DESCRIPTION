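Package: ifcpollen
Title: Pollen Morphometry from Imaging Flow Cytometry Galleries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open, tested reimplementation of an imaging-flow-cytometry
    workflow for high-throughput pollen size measurement: synthetic
    brightfield object galleries with exact ground truth, object and
    adaptive-erode segmentation masks, six size features in micrometres
    (area-equivalent diameter, bounding-rectangle height and width,
    best-fit-ellipse major axis, fold-tolerant geodesic length, maximum
    thickness), quality gating (debris, doublet, cropped and outlier
    removal, polar/equatorial view sorting), calibration-bead modal-size
    checks, hierarchical species size summaries, Bland-Altman method
    agreement against literature sizes, and Blomberg's K phylogenetic
    signal with a randomization test on dated phylogenies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    ape,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    phytools,
    picante,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
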