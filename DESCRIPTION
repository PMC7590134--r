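Package: imucodec
Title: Lossless Predictive Compression of Human-Movement IMU Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Lossless compression of multi-channel inertial measurement unit
    (IMU) time series such as body-worn accelerometer and gyroscope recordings.
    Implements a family of causal autoregressive predictors (delta coding,
    linear extrapolation, 2nd- to 5th-order polynomial regression, and natural
    cubic-spline extrapolation) evaluated in deterministic Q16.16 fixed-point
    arithmetic, with Golomb-Rice entropy coding of the prediction residuals
    and a self-describing container format. Also provides baseline
    representations (fixed-width CSV, raw binary, DEFLATE), a-posteriori
    L1-optimal autoregressive and multivariate autoregressive reference
    models fitted by exact weighted-median coordinate descent, a synthetic
    IMU corpus generator, and a benchmarking harness with compression-ratio
    reports, Friedman/Nemenyi rank comparisons and ANOVA/Tukey group tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
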