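Package: fetseg
Title: Automated 3D U-Net Detection and Segmentation of Amino-Acid PET Brain Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated two-step pipeline for lesion detection and
    segmentation of 18F-FET PET brain volumes: synthetic dynamic PET phantom
    simulation with known lesion masks, semi-automatic reference segmentation
    by contralateral-background thresholding (1.3 x background over a 10 cm3
    spherical VOI), volumetric preprocessing with contour enhancement and 3D
    affine augmentation, a 3-level volumetric U-Net trained with a soft Dice
    loss under Adam, morphological dilation plus adaptive hemispheric-swap
    thresholding of the predicted mask, and voxel- and lesion-level evaluation
    (Dice, sensitivity, specificity, predictive values with Wald intervals).
    All convolutional network operations are implemented natively (Rcpp and
    RcppArmadillo) so the pipeline runs end-to-end on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
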