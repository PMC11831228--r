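Package: octccr
Title: Complex Conjugate Artifact Removal for Frequency-Domain OCT with
    Phase-Aware Conditional GANs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for removing the complex conjugate artifact from
    frequency-domain optical coherence tomography (FD-OCT) B-scans with a
    phase-aware conditional generative adversarial network. Includes a
    physics-based fringe simulator that emulates paired zero-delay-shift
    acquisitions (artifact-corrupted input and artifact-free ground truth
    of the same sample), the FD-OCT image-formation chain (FFT
    reconstruction, log-scale intensity and phase grayscale images with
    invertible normalization), a U-Net generator and convolutional
    discriminator trained with an L1-weighted adversarial objective and a
    perceptual feature loss, and an evaluation harness (PSNR, SSIM,
    Frechet distance with subsample error bars, variance-ratio F-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
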