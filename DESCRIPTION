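Package: axmwi
Title: Simulated Radar Microwave Imaging of Axillary Lymph Nodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation of an ultra-wide-band radar microwave
    imaging system for axillary lymph node detection. Builds 2D dispersive
    tissue phantoms of the axillary region (single-pole Debye media, layered
    skin/adipose/muscle anatomy, bean-shaped lymph nodes, tiled dielectric
    heterogeneity), runs a finite-difference time-domain forward solver with
    convolutional PML boundaries to produce monostatic backscatter channel
    data, removes the dominant skin artifact by average subtraction or
    adaptive multichannel filtering, reconstructs backscattered-energy images
    with delay-and-sum, delay-multiply-and-sum and their channel-ranked
    variants, and scores detections with signal-to-clutter, signal-to-mean,
    max-to-max, full-width-at-half-maximum and localization-error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
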