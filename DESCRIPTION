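Package: nocipipe
Title: Multimodal Intraoperative Nociception Monitoring Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating intraoperative nociception from simultaneously
    recorded ECG, photoplethysmography (PPG) and EEG. Provides a synthetic
    operating-room session simulator with known ground truth; sliding-window
    feature extraction (EEG band powers, high-frequency heart-rate-variability
    spectral power, PPG pulse amplitude and area under the curve); online
    feature normalization that blends group-population and accumulating
    per-patient statistics; multilayer-perceptron and LSTM regressors trained
    against expert nociception assessments; and an evaluation battery covering
    inter-rater agreement (ANOVA, ICC, Bland-Altman), surgical-event response
    analysis and per-patient ROC discrimination of noxious stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
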