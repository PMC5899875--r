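Package: cryoreg
Title: Multiscale Registration and Analysis of Whole-Animal Cryo-Imaging, MRI and Histology Volumes
Version: 0.1.0
Authors@R:
    person("Cryoreg", "Developers", email = "cryoreg@example.org", role = c("aut", "cre"))
Description: Registration, evaluation and analysis toolkit for multimodal
    whole-animal imaging studies. Implements block-matching rigid/affine
    registration with absolute normalized cross-correlation and trimmed
    least-squares model fitting, B-spline free-form-deformation nonrigid
    registration driven by normalized mutual information with bending-energy
    and log-Jacobian regularization, edge-based 2D histology-to-blockface
    registration, CT Hounsfield-unit based tissue volume-change estimation,
    quantitative registration metrics (Dice, volume difference, mean surface
    distance, landmark error), connected-component tumor quantification, and a
    seeded synthetic phantom generator with ground-truth deformations for
    validation. Volumes are read and written as NIfTI-1 or uncompressed
    multipage TIFF with physical voxel spacing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
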