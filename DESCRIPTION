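Package: placidoedge
Title: Sub-Pixel Edge Detection for Corneal Placido Ring Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-to-fine sub-pixel edge detection for corneal Placido ring
    images and other circular-edge targets. A radially modulated Mexican Hat
    wavelet front-end accumulates multi-scale, multi-position convolution
    responses, fuses them with dispersion-derived weights and sharpens the
    result with a difference-of-Gaussians filter to obtain interference-
    suppressed coarse edges. Candidate pixels are then localized to sub-pixel
    accuracy by inverting the ideal step-edge model of 9x9 Zernike moment
    templates, and gated by two adaptive thresholds: a gray-level threshold
    built from local gradient and variance statistics, and a distance
    threshold driven by Hessian principal curvature. Includes synthetic
    fixture generators (binary circle, noisy variants, Placido ring phantoms
    with eyelash and specular interference), an evaluation module reproducing
    circle-accuracy error statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
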