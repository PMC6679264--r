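Package: speckleAD
Title: Anisotropic Diffusion Despeckling for Speckle-Corrupted Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removal of multiplicative (speckle) noise from 2-D grayscale and
    RGB images by anisotropic diffusion. Implements a gray-level/noise-
    standard-deviation indicator-driven diffusion model for the compressed
    speckle model I0 = I + sqrt(I)*n, an improved variant that diffuses only
    tangentially at detected edges, explicit finite-difference solvers with
    conservative face fluxes and zero-flux boundaries, blind iteration
    stopping criteria based on residual-noise kurtosis and image-noise
    correlation, quadratic post-processing through Gaussian histogram
    specification, Perona-Malik and gray-level-indicator baselines, image
    quality metrics (dynamic-range PSNR, MAE, SSIM), an analytic Shepp-Logan
    phantom generator and seeded speckle corruption for reproducible
    benchmarking, and parameter sweep / grid-search utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
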