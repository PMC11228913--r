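Package: crystrack
Title: Time-Resolved Tomographic Analysis of Dissolving Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the dissolution of individual soluble crystals from
    time series of 3D tomographic gray-value volumes. Segments crystals from
    an insoluble spacer matrix (minimum cross-entropy thresholding, circular
    field-of-view crop, connectivity-6 object labeling), measures per-object
    morphometry (volume, surface area, sphericity, centroid), tracks each
    crystal through time including breakup lineage, and estimates the
    individual dissolution rate InDR(t) = -rho * V'(t) / A(t) from
    quadratically smoothed volume and surface trajectories. Includes a
    synthetic 4D phantom generator (shrinking octahedra, pyramids and
    spheres among inert spacers under a top-down saturation front) with
    exact ground truth for end-to-end validation, plus population-level
    size-class statistics and spatial rate maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
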