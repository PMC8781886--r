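Package: rppgnet
Title: Remote Photoplethysmography with Temporal Central-Difference
    Convolution and 3D Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures heart rate from facial video by recovering the remote
    photoplethysmography (rPPG) signal with a lightweight spatiotemporal
    network built on temporal central-difference convolution (3DCDC-T) and a
    3D convolutional-block attention module (3D-CBAM). Includes landmark-driven
    cheek and forehead region-of-interest extraction, a negative Pearson
    correlation training loss with an Adam optimiser, band-pass filtering and
    windowed spectral heart-rate estimation with agreement metrics, and a
    synthetic pulse-video generator so the whole pipeline can be exercised
    end to end without clinical recordings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    yaml,
    png,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
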