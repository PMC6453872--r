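Package: radbone
Title: Calibrated Bone Density and Directional Fractal Texture from Knee Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative analysis of subchondral bone from plain knee
    radiographs: aluminum step-wedge calibration of region-of-interest mean
    grayscale to aluminum-equivalent thickness (GV_mmAl), directional fractal
    signature analysis (blanket method) yielding vertical and horizontal
    fractal dimensions at four spatial scales, normality-routed group
    statistics with post hoc tests, and elastic-net logistic classification
    of osteoarthritis and bone-marrow-lesion status with leave-one-out
    cross-validated hyperparameter search and DeLong ROC confidence
    intervals. Includes a seeded synthetic-radiograph generator (fractional
    Brownian trabecular texture, rendered step wedge, simulated clinical
    post-processing) so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
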