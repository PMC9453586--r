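Package: labforecast
Title: Forecasting Near-Future Abnormal Laboratory Values in the ICU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting which intensive-care laboratory values
    will fall outside their reference range at the next 4-hour time step,
    from sparse, irregularly sampled lab histories plus demographics.
    Includes a synthetic cohort generator emulating the statistical shape
    of ICU lab extracts, a preprocessing chain (4-hour discretization,
    frequency-derived sample-and-hold, Tukey-fence outlier removal,
    k-nearest-neighbour/SVD/mean imputation), a moving-window dataset
    builder for multilabel next-step classification, six predictor
    families (LSTM, CNN, dual-stream M-CNN, transformer with learned time
    encoding, temporal convolutional network, gradient boosting) behind a
    single train/predict contract, micro-averaged evaluation metrics, and
    a two-cohort cross-generalization experiment harness.
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
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
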