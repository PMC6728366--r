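Package: neuromast
Title: Quantifying Hair-Cell Orientation, Concentricity and Polarity in
    Zebrafish Neuromasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Circular-statistics toolkit for planar cell polarity phenotypes in
    the zebrafish lateral line. Distinguishes random (PCP-type) from concentric
    (Wnt-type) hair-cell misorientation by fitting an ellipse to cell centers,
    projecting each cell to the nearest boundary point and testing the signed
    deviation of its polarity axis from the local tangent against uniformity.
    Also provides axial von Mises fitting, quadrant binomial and Fisher axis
    tests, kinocilium pair-opposition scoring, progenitor division-angle
    geometry, cortical angular-intensity polarity profiling with Monte Carlo
    fit errors, support-cell moment-ellipse orientation analysis, and a
    seeded synthetic-neuromast generator so every stage is verifiable without
    raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
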