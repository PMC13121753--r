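Package: jzmorph
Title: Quantitative Analysis of Junctional Zone Morphogenesis from Live and Fixed Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory and image analytics for epithelial morphogenesis of the
    avian junctional zone, the region where primary and secondary neurulation
    meet. Provides track registration and origin subtraction,
    toward-midline/ventral displacement components, region classification,
    decile displacement profiles, displacement-weighted polar directionality
    histograms, per-cell and cortical (polar-coordinate, 80%-radius) intensity
    scoring on segmented 2-D projections, planar-cell-polarity junction
    classification and ML/AP intensity ratios, background-referenced nuclear
    positivity classification, dorsoventral relative-depth statistics, apical
    constriction normalization/alignment and ingression detection, thin
    wrappers for the t and Kolmogorov-Smirnov comparisons, and synthetic-data
    generators with exact ground truth so every stage is verifiable without
    raw microscopy.
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
    graphics,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
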