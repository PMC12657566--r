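Package: nirsconnect
Title: Resting-State fNIRS Functional Connectivity and Bayesian Degree Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for resting-state functional near-infrared
    spectroscopy (fNIRS): conversion of dual-wavelength optical intensities to
    oxy-/deoxy-hemoglobin concentration changes (optical density, temporal
    derivative distribution repair, short-separation channel regression, scalp
    coupling index screening, spherical-spline channel interpolation, the
    modified Beer-Lambert law, negative-correlation enhancement, and band-pass
    filtering), epoch-based binarized connectivity graphs with channel-wise
    degree, and a Bayesian multilevel Poisson model of degree with
    group-by-session inference via average marginal posterior predictions,
    highest density intervals, and region-of-practical-equivalence decision
    rules. Includes a synthetic-data generator with known latent connectivity
    and known generative coefficients so the whole pipeline is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rjags,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
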