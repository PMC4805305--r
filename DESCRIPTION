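Package: keranet
Title: Keratin Network Morphometry, Motility and Cell Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of keratin intermediate filament networks
    in epithelial cells. Implements a branch-length morphometry pipeline for
    confocal images (Gaussian denoising, optimally oriented flux enhancement,
    thresholding, topology-preserving thinning, filament-graph reconstruction
    with branch-point merging and geometric smoothing), motion analysis of
    keratin time-lapse recordings (normalized cross-correlation block
    matching, speed heat maps, motion-compensated bulk-flow turnover maps,
    circular cell-shape normalization), and viscoelastic power-law fitting of
    atomic force microscopy indentation curves (F = A delta^b) and magnetic
    tweezers creep responses (J(t) = J0 (t/t0)^beta). A seeded synthetic-data
    module generates filament phantoms, advected time-lapse movies,
    force-distance curves and bead tracks with known ground truth so every
    stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    withr,
    minpack.lm,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
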