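Package: ptychostream
Title: Streaming Ptychography with Iterative Phase Retrieval and an
    Online Neural-Network Surrogate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for AI-enabled streaming
    ptychography. Provides a coherent-diffraction forward model with
    defocused donut probes, spiral scans and Poisson counting noise; a
    regularized Ptychographic Iterative Engine (rPIE) with multiple probe
    modes for ground-truth phase retrieval; a lightweight fully
    convolutional encoder-decoder network that maps single diffraction
    frames to real-space phase patches; continual (online) training with
    cyclic learning rates and mismatch-triggered retraining; stitching of
    per-position inferences from irregular scan grids; and evaluation
    metrics (structural similarity, overlap/dose sweeps, Fourier ring
    correlation resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
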