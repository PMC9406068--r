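Package: adaptIMPT
Title: Structure-Propagation Uncertainty in Online Adaptive Proton Plan Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation study of strategies for integrating deformable-
    image-registration (DIR) contour-propagation uncertainty into online adaptive
    intensity-modulated proton therapy (IMPT) plan optimization. Provides synthetic
    anatomical phantoms (abdominal-stereotactic and head-and-neck templates) with
    per-fraction anatomical change and simulated multi-algorithm DIR contour
    ensembles; contour-ensemble algebra (union, intersection, voxel agreement maps,
    exact-level agreement substructures, conservative combination); an analytic
    spot-scanning proton dose model with sparse influence matrices and setup/range
    error scenarios; worst-case (minimax) constrained spot-weight optimization
    implementing six adaptation strategies (single-DIR, multi-DIR worst-case,
    conservative, probabilistic, reference, no adaptation); and a plan-quality
    scoring system with reference differencing, cohort aggregation, and
    scoring-weight sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
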