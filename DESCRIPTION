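Package: capsrecon
Title: Capsule-Network Decoding and Reconstruction of Visual Stimuli from fMRI
Version: 0.1.0
Authors@R: person("capsrecon", "maintainers", email = "capsrecon@example.org",
    role = c("aut", "cre"))
Description: Two-stage decoding pipeline that reconstructs small grayscale
    image stimuli from voxel responses in early visual cortex.  Stage one
    trains a capsule network (convolutional feature extraction, dynamic
    routing by agreement, margin loss, and a fully connected reconstruction
    decoder) so that a 16-dimensional "digit capsule" carries an equivariant
    description of each stimulus.  Stage two selects voxels by the in-sample
    coefficient of determination of a per-voxel linear encoding model on the
    capsule features, and trains a three-layer network mapping the selected
    voxels back to the capsules; decoding an unseen trial takes the longer
    predicted capsule through the frozen decoder.  Includes a synthetic
    stimulus/voxel generator with recorded ground truth, reconstruction
    metrics (MSE, pixel correlation, SSIM), cross-validated evaluation,
    capsule perturbation sweeps and gradient-based voxel attribution, and a
    staged command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
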