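Package: weakreg
Title: Weakly-Supervised Deformable Multimodal Image Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains convolutional networks to predict dense displacement
    fields (DDFs) that align pairs of 3D multimodal volumes, supervised only
    by corresponding anatomical label masks through multiscale soft-Dice or
    cross-entropy similarity plus bending-energy regularisation.  Includes
    differentiable volume warping, affine augmentation and composition,
    deformation diagnostics (Jacobian determinants, displacement and
    gradient statistics), landmark-centroid TRE and Dice evaluation, a
    two-modality synthetic phantom generator with known ground-truth
    deformations, and a command-line interface for simulate / train /
    register / evaluate workflows on NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
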