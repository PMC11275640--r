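Package: specbrix
Title: Vis-NIR and NIR Spectral Calibration of Soluble Solids in Fruit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A chemometrics pipeline for estimating soluble solids content
    (SSC, % Brix) of fruit from visible-near-infrared and near-infrared
    diffuse reflectance spectra. Provides absorbance computation from raw
    detector counts, Savitzky-Golay second-derivative preprocessing, a
    from-scratch NIPALS partial least squares regression with PRESS-based
    latent-factor selection by an F-ratio rule, standard calibration
    validation metrics (R2, RMSE, RPD, slope/offset/bias), cross-variety
    model transfer evaluation, a spectrometer noise-level statistic over
    exposure-by-integration acquisition grids, and a synthetic strawberry
    spectra generator for end-to-end testing of the whole workflow.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
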