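Package: carposeg
Title: Carpal Bone Segmentation, Mesh Metrics and Freeze-Thaw Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments a small carpal bone (scaphoid-like object) from
    CT-style volumes in Hounsfield units by threshold-connected region
    growing, hole filling and Laplacian level-set refinement, with both a
    tight (native-surface) workflow and a prosthesis-ready smooth workflow
    that erodes the mask and refills the trabecular interior at cortical
    intensity before re-segmentation. Quantifies the resulting triangle
    meshes: divergence-theorem volume, trimmed iterative-closest-point rigid
    registration, signed surface-distance maps with summary statistics, and
    joint-space thickness between articulating bones. Includes a synthetic
    CT phantom generator with analytic ground truth so the whole pipeline is
    testable without cadaver data, and paired-comparison statistics
    (paired t-test, confidence interval, Cohen's d, relative differences)
    for frozen-versus-thawed volume tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
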