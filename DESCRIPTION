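Package: mraseg
Title: Multiresolution Transform-Based Segmentation of Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiresolution analysis for region-of-interest segmentation in
    2D grayscale medical images. Implements from scratch a 2D discrete
    wavelet transform (Haar and Daubechies filter banks, periodic extension),
    the finite Radon and finite ridgelet transforms on prime-sized blocks,
    and a wrapping-based fast discrete curvelet transform built on Meyer-type
    radial and angular windows forming an exact frequency partition of unity
    (tight frame). The transforms are composed into a
    threshold-denoise-threshold segmentation pipeline with
    connected-component region extraction, equivalent-diameter measurement,
    and the standard fidelity metrics (MSE, PSNR, SNR). A synthetic
    NEMA-IEC-style body phantom generator with a Gaussian noise model makes
    every stage testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    png,
    tiff,
    yaml,
    optparse,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
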