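Package: ppgplus
Title: Blood-Pressure Level Classification from Photoplethysmography via
    EEMD and Hilbert-Huang Spectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired photoplethysmography (PPG) and arterial
    blood-pressure (ABP) records, denoises and de-drifts PPG with ensemble
    empirical mode decomposition (EEMD), converts PPG and its first and
    second derivatives into Hilbert-Huang time-frequency spectrograms,
    composes them into three-channel "PPG+" images labelled with JNC7
    blood-pressure classes derived from the paired ABP waveform, and trains
    a compact convolutional classifier under stratified k-fold
    cross-validation. Includes analytic parameter and multiply-accumulate
    counting for fine-tuned AlexNet/ResNet heads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    png,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
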