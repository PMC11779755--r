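Package: shapescission
Title: Stimulus Generation and Analysis for Shape-Transformation Drawing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing drawing experiments on the
    perception of shape transformations. Provides closed-contour primitives
    (uniform arc-length resampling, normalization, Procrustes rotation), five
    parametric contour deformations (twist, bloat, fisheye, shear, rotation)
    with magnitude calibration in a perceptual shape-similarity embedding,
    random-polygon and radial-frequency shape generators, constrained factorial
    stimulus sampling, a synthetic-participant drawing simulator, and the
    difference-of-distances trial statistic with its standard aggregation
    (one-sample t per condition, one-way F across factors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
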