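Package: blob3d
Title: Small-Blob Detection in 3D Volumes via Hessian Convexity and
    Contrastive Unpaired Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis, denoising and detection of small dark blobs (such as
    glomeruli in cationic-ferritin-enhanced MRI) in 3D grayscale volumes.
    Provides a phantom generator based on 3D elliptical Gaussians with
    ground-truth masks and centers, per-voxel Hessian convexity analysis and
    blobness scoring, a one-sided contrastive unpaired image-to-image
    translation model (3D convolutional generator and PatchGAN discriminator
    with patchwise contrastive, convexity-consistency and intensity-
    distribution losses) for denoising, blob identification by intersecting
    the Hessian convexity mask with the translated blob mask, and a
    detection/segmentation evaluation suite (detection error rate, matched
    precision/recall/F-score, Dice, IoU, blobness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
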