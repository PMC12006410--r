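Package: neoquant
Title: Quadrant-Based Neointima Quantification for Stented-Vessel OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of intravascular optical coherence
    tomography (OCT) pullbacks after coronary stent implantation:
    pixelwise segmentation of lumen, neointima and stent struts,
    lumen-centered partition of each frame into four clockwise quadrants,
    per-quadrant neointimal tissue classification (homogeneous,
    heterogeneous, neoatherosclerosis, not analyzable) with a calibrated
    confidence chain (test-time augmentation, temperature sharpening,
    fusion of neighbouring quadrants), vessel morphometrics (neointimal
    thickness, lumen radius, minimal lumen diameter, uncovered struts,
    stent boundaries), and an evaluation suite (Dice, Fleiss kappa,
    reliability curves, patient-grouped cross-validation). A seeded
    synthetic phantom generator with exact ground truth makes the whole
    pipeline exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    ranger,
    nnet,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
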