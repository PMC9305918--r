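Package: vdmkit
Title: Vascular Deformation Mapping of Aortic Growth with Synthetic
    Phantom Validation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies three-dimensional growth of the thoracic aorta from
    serial CT-angiography-like volumes by vascular deformation mapping (VDM):
    a three-stage deformable registration (rigid alignment, rigidity- and
    bending-regularized centerline alignment, fine B-spline registration)
    followed by mesh-based growth metrics (per-face area ratio and per-vertex
    deformation in the surface-normal direction). Includes a synthetic
    aortic-phantom generator with analytic ground-truth deformations,
    boundary-image ground-truth field synthesis, robustness perturbations
    (Gaussian noise with contrast-to-noise calibration, slice-thickness
    resampling, bulk rigid motion, respiratory translation), and
    centerline-based maximal-diameter-change analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
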