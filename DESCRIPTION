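Package: sonoseg
Title: Multi-Target Neck Ultrasound Segmentation with an Attention-Pyramid
    Nested U-Net and Lovasz-Softmax Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-class semantic segmentation of transverse neck ultrasound
    frames (background, thyroid, trachea, intra-thyroid nodules-or-vessels,
    esophagus, carotid artery) and downstream 3D label-volume visualization.
    Provides a nested U-Net (U-Net++) segmentation network augmented with a
    pyramid pooling module on the deepest encoder feature and attention gates
    on the decoder skip bundles, trained with the Lovasz-Softmax loss (the
    tight convex surrogate of the per-class Jaccard loss), together with a
    confusion-matrix metric suite (Dice, IOU, mIOU, pixel accuracy, per-class
    pixel accuracy), a speckled neck-phantom simulator for fully synthetic
    end-to-end testing, non-local-means denoising and seeded augmentation,
    a training/ablation harness, and label-volume surface meshing with
    NIfTI/PLY/STL export. All tensor operations run on a package-internal
    reverse-mode autodiff engine with C++ kernels; no external deep-learning
    framework is required.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
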