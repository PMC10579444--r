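Package: coronary3d
Title: Synthetic Coronary Trees, Cone-Beam Angiogram Simulation, and
    Multi-Stage 3D Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying 3D reconstruction of right coronary artery
    trees from uncalibrated 2D angiography-like projections. Provides a
    randomized generator of anatomically plausible coronary-tree geometries
    (centerline splines, linear radius taper, Gaussian-profile stenoses,
    geometric augmentation), a cone-beam projector producing binary
    512x512 angiogram silhouettes with Euclidean distance-transform
    preprocessing, a multi-stage regression network (shared convolutional
    backbone with separate centerline and per-branch radius perceptron
    heads) trained with an arclength-regularized loss, a classical
    epipolar-geometry reconstruction baseline, and the evaluation metrics
    (centerline RMSE, radius RMSE, stenosis MAE, vessel-length MAE) used
    to compare them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
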