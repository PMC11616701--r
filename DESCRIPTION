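Package: vdcyto
Title: Image-Based Viscoelastic Deformability Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis toolkit for viscoelastic deformability cytometry:
    detection of single cells in high-speed bright-field frames from parallel
    microchannels, per-cell deformability and companion shape/intensity
    features, density-contour gating of populations in (area, deformability)
    space, rare-cell quantification with exact binomial intervals, and the
    statistical comparisons used for mechanical phenotyping. Includes a
    synthetic frame generator that renders bullet-shaped deformed cells with
    exact geometric ground truth, so the full pipeline is testable end-to-end
    without an acquisition system, plus small utilities for shear-thinning
    (Carreau) viscosity and dimensionless flow numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    mgcv,
    jsonlite,
    minpack.lm,
    tiff,
    png,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
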