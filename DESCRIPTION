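Package: chemocal
Title: Chemometric Calibration of ATR-IR Spectra for Low-Dose Pharmaceutical Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying an active pharmaceutical
    ingredient in tablets and granules from attenuated total reflectance
    infrared (ATR-IR) spectra. Provides spectral pretreatment (standard
    normal variate, area normalization, Savitzky-Golay derivatives),
    Kennard-Stone and stratified calibration/validation splitting, a
    NIPALS partial least squares regression engine with cross-validated
    latent-factor selection, model-grid screening and ranking, validation
    metrics (RMSEC/RMSECV/RMSEP, bias, R-squared variants, residual
    diagnostics, paired method comparison), HPLC reference-method
    utilities, and a synthetic spectrum generator emulating seven-level
    concentration series of chlorpheniramine maleate formulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
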