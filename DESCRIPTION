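Package: embryocast
Title: Recursive Forecasting of Embryo Development in Time-Lapse Videos
Version: 0.1.0
Authors@R: person("Embryocast", "Developers", email = "maintainer@embryocast.dev",
    role = c("aut", "cre"))
Description: Toolkit for forecasting human embryo development in time-lapse
    incubator videos. Provides a synthetic annotated embryo video simulator
    (cleavage-stage and blastocyst-stage windows, transfer and avoid
    trajectory profiles), preprocessing of frames into normalized
    multi-channel tensors with sliding-window subsequences, a convolutional
    LSTM next-frame predictor with dual convolutional output heads trained by
    binary cross entropy, two recursive multi-hour forecasting strategies
    (forecast-till-end and rolling next-seven-frames), a U-Net embryo
    cropper for foreground matting, and a video-quality evaluation harness
    (PSNR, SSIM, and a Frechet video distance over pluggable sequence
    embeddings). The neural-network compute core (convolutions, ConvLSTM
    recurrence, U-Net encoder-decoder, backpropagation, Adam) is implemented
    in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
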