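Package: eyemosaic
Title: Retinal Sampling-Station Images of Animal Eyes from Photographs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transforms a digital photograph (or a set of gray-scale filter
    photographs) into an approximation of the image available at the
    sampling-station stage of a nonhuman eye. Sampling stations are laid out
    either on a regular hexagonal grid (scanning mode) or on concentric
    elliptical rings projected from a fixed viewpoint, with interommatidial
    angles that may grow quadratically with eccentricity. Each station
    averages the scene through a Gaussian acceptance-angle profile and the
    output mosaic fills every station's cell with its averaged color.
    Includes per-channel spatial parameters, recombination of gray-scale
    filter photographs through a weighting matrix, and a
    modulation-transfer-function validation harness based on square-wave
    gratings.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jpeg,
    png,
    stats,
    tiff,
    tools
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
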