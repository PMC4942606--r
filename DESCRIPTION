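Package: snomchemo
Title: Chemometric Analysis of SNOM-IR Transmission Images and ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end chemometrics pipeline for near-field infrared
    microscopy (SNOM-IR) transmission images and attenuated total reflection
    Fourier-transform infrared (ATR-FTIR) spectra of cervical cytology samples.
    Reduces per-wavelength transmission images to spectrum-like signals by
    column-wise averaging, quantifies biomarker absorption areas and their
    percentage change relative to normal cells, and fits principal component
    models with Hotelling T-squared and Q-residual diagnostics. For spectral
    classification it provides Kennard-Stone sample splitting, Mahalanobis
    linear discriminant analysis, PCA-LDA with validation-driven component
    selection, and successive projections algorithm (SPA) variable selection
    with the G cost function. A synthetic-data module generates transmission
    image sets and band-structured spectra with known class effects so the
    whole pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
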