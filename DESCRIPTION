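Package: synthmri
Title: Synthesis of Complex-Valued Multicoil MRI Data from Magnitude-Only Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning magnitude-only MR images into complex-valued
    multicoil k-space suitable for training and evaluating physics-based
    reconstruction networks. Provides seeded brain-like phantom generation,
    the Cartesian MRI signal model (centered unitary FFTs, coil sensitivity
    application, equispaced undersampling masks, SENSE forward/adjoint
    operators), ESPIRiT coil-sensitivity estimation, a conditional GAN
    (U-Net generator, 70x70 patch discriminator) that learns
    magnitude-to-phase translation, baseline phase models (zero, random,
    sinusoidal), an unrolled variational-network reconstruction model, and
    reconstruction quality metrics (PSNR, NMSE, SSIM) with a phase-model
    comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
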