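Package: dxduo
Title: Dual-Probe Diffracted X-Ray Blinking and Tracking Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-labeled diffracted X-ray blinking (DXB)
    and diffracted X-ray tracking (DXT) experiments, in which gold and zinc
    oxide nanocrystal probes attached to two domains of a single protein are
    monitored simultaneously on a photon-counting detector. Predicts and
    labels Debye-Scherrer rings for the two probes, computes per-pixel
    intensity autocorrelation functions and exponential decay constants,
    decomposes decay-constant distributions into low- and high-mobility
    Gaussian components, compares conditions with exact Wilcoxon rank-sum
    tests, tracks Laue spots into twisting/bending angular trajectories, fits
    anomalous-diffusion mean squared displacement models, and builds
    two-dimensional motion maps with projections, hotspots and subtraction
    maps. Includes a synthetic-data generator with known ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
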