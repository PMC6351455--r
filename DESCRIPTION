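Package: nirsdecode
Title: Decoding Driving Difficulty from fNIRS Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for decoding driving difficulty
    (construction vs. non-construction road sections) from multichannel
    deoxyhemoglobin (HbR) time series recorded with functional near-infrared
    spectroscopy (fNIRS) during an n-back speed-regulation dual task. Includes
    a forward simulator (block design, double-gamma hemodynamics with a
    configurable difficulty-by-working-memory-load interaction, physiological
    and motion noise, modified Beer-Lambert forward model, driving behavior),
    preprocessing (optical density, MBLL inversion, coefficient-of-variation
    channel rejection, least-squares FIR low-pass filtering, behavioral
    segment exclusion, train-fold PCA denoising), behavioral metrics
    (n-back target-speed tracks, speed-error rates, steering reversal rates),
    nested cross-validated L2-penalized logistic decoding with condition
    dissimilarity matrices, and channel-wise Tjur R-squared predictivity maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
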