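Package: wranet
Title: Wavelet Residual Attention Networks for Biomedical Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a U-shaped encoder/decoder segmentation network whose
    downsampling is a one-level 2D discrete wavelet transform retaining only the
    low-frequency (LL) subband, with residual attention gates on the skip
    connections and a weighted binary cross-entropy plus Dice hybrid loss.
    Provides validated quadrature-mirror filter banks for 21 orthogonal and
    biorthogonal wavelet families, forward and inverse separable periodized
    2D-DWT for multi-channel feature maps, a CPU training loop with the Adam
    optimizer, fivefold cross-validation, segmentation metrics (Dice, IoU,
    precision, sensitivity), and a reproducible synthetic lesion-image
    generator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
NeedsCompilation: yes
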