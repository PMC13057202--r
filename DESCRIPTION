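Package: mangroveCarbon
Title: Species-Level Mangrove Carbon Stock Estimation from Multispectral
    Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for species-level carbon assessment of mangrove
    stands from five-band (blue, green, red, red-edge, near-infrared)
    multispectral rasters and a digital surface model. Computes spectral
    vegetation indices, a canopy height model (inverse-distance-weighted
    terrain interpolation subtracted from the surface model), and
    gray-level co-occurrence texture metrics; classifies species with a
    Gaussian maximum-likelihood classifier over configurable feature
    combinations scored by confusion-matrix accuracies; converts per-tree
    field measurements to plot carbon through a registry of allometric
    equations; fits species and species-combination linear carbon models
    with Pearson screening, variance-inflation filtering and leave-one-out
    cross-validation; and maps above-ground, below-ground and total carbon
    per pixel. A synthetic-scene generator with known species labels,
    spectra, heights and allometry supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
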