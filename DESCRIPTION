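Package: cpmorph
Title: Morphometrics of Capitate-Peg Sensillum Neurons from Volume EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Skeleton-based morphometric analysis of insect olfactory receptor
    neurons segmented from volume electron microscopy. Provides SWC skeleton
    geometry (arc-length parameterisation, orthogonal projection, basal
    extrapolation), axial cross-sectional-area profiling of binarised
    structures (point-cloud projection, normalised-position histogram with
    volume-conserving rescaling, Gaussian smoothing), varicosity and connector
    calling (prominence-based peak detection, full width at half maximum),
    mitochondrial occupancy, soma-depth and cuticle-encapsulation metrics, a
    hierarchical Bayesian allometric regression of inner-dendrite volume on
    outer-dendrite surface area with PSIS-LOO model comparison, the matching
    group-comparison statistics, and synthetic-geometry generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    optparse
Config/testthat/edition: 3
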