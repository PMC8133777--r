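Package: epimech
Title: Tissue-Scale Quantification of Epithelial Cell Morphology and Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for tissue-scale patterning of epithelial
    cell morphology, built around the Drosophila wing-disc pouch. Implements
    triangle-method morphometry of cell elongation with curvature
    deprojection, exact decomposition of tissue shear into cellular
    contributions (cell-shape change, T1 transitions, divisions, extrusions,
    correlations), ESCA inference of normalized tissue stresses and the
    elastic-constant ratio from circular laser ablations, and an active
    nematic continuum model with mechanosensitive feedback, including the
    radial boundary-value problem and parameter fitting. Ships a synthetic
    tissue generator (ring-lattice epithelium, domed height fields, tracked
    timelapses with biased T1 events, forward-model ablation contours) so
    every analysis stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
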