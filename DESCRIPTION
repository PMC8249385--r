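Package: polsynth
Title: Computational Polarization-Sensitive OCT Contrast Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesizes polarization-sensitive optical coherence tomography
    (PS-OCT) contrasts -- degree of polarization uniformity (DOPU) and phase
    retardation -- from single-polarization OCT intensity B-scans using a
    pix2pix-style conditional generative adversarial network whose generator
    loss is augmented with the structural similarity index (SSIM). Includes a
    layered birefringent tissue phantom simulator producing co-registered
    intensity/DOPU/retardation triplets with cancer-versus-normal class
    structure, the image conditioning and dataset partitioning pipeline
    (margin cropping, square tiling, 16-to-8-bit conversion, 8:1:1 splits),
    intensity-thresholded (masked) SSIM evaluation with jet-colormap overlay
    rendering, and downstream validation via cancer/normal classifiers
    (ROC/AUC), penultimate-activation extraction and t-SNE embedding. The
    GAN, the reduced residual classifier, ROC/AUC and t-SNE are implemented
    from first principles on top of Rcpp convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
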