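Package: auriclesym
Title: Surface-Based Auricle Morphometry and Bilateral Symmetry Analysis
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-precision surface-based morphometry of the human auricle
    (external ear) from triangulated head meshes. Establishes a head-centric
    coordinate frame from a mirror-registration symmetry plane and a
    cylinder-fit cranial axis, measures seven geometric auricle parameters
    (length, width, protrusion distance, auriculocephalic angle, inclination
    angle, and superoinferior/posteroanterior position differences), emulates
    landmark-based manual anthropometry with observer noise, and evaluates
    bilateral symmetry with reliable-change-index thresholds, per-individual
    asymmetry classification and group-level tests. Includes a parametric
    synthetic head/ear generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
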