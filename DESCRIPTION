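Package: hexdemosaic
Title: Demosaicing Toolkit for Hexachromatic Color-NIR Image Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for single-chip hexachromatic
    imagers that sample three visible and three near-infrared (NIR) channels in
    a checkerboard arrangement over vertically stacked photodiodes. Provides the
    sensor forward model (masked sampling with optional noise), synthetic scene
    generators for testing, three reconstruction methods (checkerboard-aware
    bilinear interpolation, a residual CNN, and a hybrid CNN-transformer with
    mask-biased token attention, transposed channel attention and gated
    feed-forward blocks), supervised and sensor-consistency training with a
    progressive patch-size curriculum, and fidelity plus task-based evaluation
    metrics (MSE, PSNR, 95th-percentile DSSIM and CIEDE2000, contrast-to-noise
    ratio, edge rise distance). Networks are trained with a compact built-in
    reverse-mode autodiff engine; convolution kernels are implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    farver,
    stats,
    utils,
    grDevices,
    yaml,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
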