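Package: dsenn
Title: Deeply Supervised Efficient Networks for Remote Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the blood-volume pulse (remote photoplethysmography,
    rPPG) from facial video with a lightweight 3D spatiotemporal
    encoder-decoder network trained under spectral deep supervision: a
    frequency-domain maximum cross-correlation (MCC) auxiliary loss applied to
    the spatially pooled activations of every intermediate layer, adding no
    trainable parameters. Includes the channel-width cost-function
    architecture search, STFT sliding-window heart-rate evaluation with
    RMSE/MAE/PCC and multi-run statistics, intermediate-layer visualization
    (activation tiles, temporal and spectral traces, learned stem filters),
    and a synthetic pulse-video generator so the full pipeline is testable
    without external datasets. The network, backpropagation and optimizer are
    implemented in R with C++ convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
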