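Package: cssdelm
Title: Motor-Imagery EEG Classification with Spatial Subspace Decomposition
    and Kernel Extreme Learning Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Small-training-sample classification of two-class motor-imagery
    EEG. Epoched multichannel trials are band-pass filtered into the
    ERD-relevant 8-31 Hz band, channels are ranked by a relative-distance
    criterion on class-conditional mu-band (8-13 Hz) power, common spatial
    subspace decomposition (CSSD) builds two class-specific spatial filter
    banks by whitening and simultaneous diagonalization, and normalized
    log-variance features are classified by an extreme learning machine
    (random hidden layer + pseudo-inverse output weights) or its kernel
    variant (a closed-form kernel ridge-type solve). Includes a synthetic
    two-class EEG generator with ground-truth event-related
    desynchronization structure, experiment sweeps over filter count and
    training fraction, broom-style tidiers, ggplot2 autoplot methods, and a
    command-line interface.
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
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
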