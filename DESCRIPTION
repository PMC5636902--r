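Package: femwalk
Title: Self-Avoiding Walk and Delayed-Feedback Models of Fixational Eye
    Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and statistical characterisation of fixational eye
    movements (FEM). Implements the non-linear delayed feedback (NDF) model of
    drift, the fading self-avoiding walk (SAW) on a lattice with quadratic and
    microsaccadic potentials, and four time-delayed SAW variants that delay the
    activation state, the readout position, the activation-setting position, or
    both. The analysis stack provides five-point velocity smoothing, elliptical
    velocity-threshold microsaccade detection with a binocular overlap
    criterion, microsaccade removal, time-averaged mean squared displacement
    (MSD) and displacement autocorrelation (DACF) estimators, log-log scaling
    exponent fits, and oscillation metrics (first-maximum lag, period, and
    feedback-delay bounds). A synthetic binocular trial generator emulates
    video-based eye-tracking recordings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
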