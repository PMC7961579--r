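Package: osmech
Title: Optical Stretcher Mechanophenotyping of Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optical-stretcher step-stress creep
    experiments on suspended single cells. Simulates seeded synthetic cohorts
    of viscoelastic, actively contracting cells and their phase-contrast axis
    traces; tracks cell geometry from rendered frame stacks by sub-pixel
    contour extraction and direct least-squares ellipse fitting; computes
    relative and elliptic deformation curves and fits passive and active
    Kelvin-Voigt models; derives shape restoration and activity labels;
    assembles per-cell feature matrices; and discriminates cell classes
    (e.g. circulating-tumor-cell candidates versus peripheral blood
    mononuclear cells) with a cross-validated random forest, held-out
    permutation importances and two-sample Kolmogorov-Smirnov comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    randomForest,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
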