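Package: femcurve
Title: Sagittal Femoral Bowing from Medullary Canal Centroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures the sagittal bowing of the femur from labelled 3D CT
    volumes of the medullary canal. Femurs are rigidly reoriented into a
    standard configuration defined by a plane tangent to the posterior
    condyles and greater trochanter, canal cross-section centroids are
    extracted at seven axial levels (5 to 35 cm above the reference plane),
    and per-segment radii of curvature are obtained from three-point circle
    fits in the sagittal plane. Includes paired pre/post radius-change
    analysis with Wilcoxon signed-rank comparisons against the contralateral
    femur, an inter-observer reliability screen, and a synthetic femur-canal
    phantom generator with known ground-truth curvature for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
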