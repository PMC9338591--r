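Package: camangle
Title: Automated Alpha-Angle Measurement for Cam-Type Femoroacetabular
    Impingement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures the alpha angle of the hip, the standard quantifier of
    femoral head-neck offset loss in cam-type femoroacetabular impingement,
    directly from a 3D binary segmentation mask of the proximal femur. The
    pipeline extracts a triangle surface from the mask, locates the femoral
    head and neck, refines the head sphere with a RANSAC fit and the neck axis
    with a minimal-circumference neck cross-section, builds a spherical
    roundness map of the head around the neck axis, and determines per-slice
    alpha angles on a radial slice group as a smoothness-regularised optimal
    cut through the map. The classical 2D circle construction (best-fit head
    circle, neck centre at the narrowest point, first-exceedance point) is
    provided as an independent oracle, parametric voxel phantoms with analytic
    ground truth support end-to-end validation, and observer-agreement
    statistics (absolute-agreement ICC with confidence intervals and
    reliability bands, Bland-Altman limits of agreement, paired t-tests,
    summary tables) reproduce the usual method-comparison workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
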