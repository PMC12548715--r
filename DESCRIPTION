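Package: axonquant
Title: Axon Density Quantification and Afferent Mapping in 3D Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies neurite (axon) density in 3D confocal fluorescence
    z-stacks: voxel-classifier bouton removal, Hessian-based tubeness
    filtering at a physical scale, hysteresis thresholding,
    topology-preserving 3D skeletonization and length-per-volume density.
    Includes systematic ROI-grid sampling of fluorescence intensity with
    region parcellation, line-intensity profiles, normalization and
    phenotype classification of retrograde tract-tracing cell counts, a
    statistics layer (correlation, t-tests, one-way and repeated-measures
    ANOVA with Tukey post hoc), and a synthetic-data generator producing
    tube phantoms, region-intensity fields and multinomial count tables
    with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
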