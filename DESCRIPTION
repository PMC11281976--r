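Package: lsrmorph
Title: Size-and-Shape Analysis of Linear Measurements with Mosimann Log
    Shape Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate size-and-shape analysis for traditional
    (linear-measurement) morphometric data, built around the workflow used
    to detect insular dwarfing signals in mammalian crania and endocranial
    structures. Provides a geometric-mean size proxy, Mosimann log shape
    ratios, allometry-free residualization against size, covariance
    principal component analysis with a deterministic axis orientation,
    and a multivariate allometry test regressing PC1 scores on the log
    geometric mean. Includes a seeded generator of synthetic allometric
    measurement tables with known ground truth, variable catalogs for
    equid crania, bony labyrinths and brain endocasts, and a config-driven
    pipeline with machine-readable output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
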