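Package: lttcal
Title: Risk-Controlling Calibration of Binary Alarm Models for Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes the outputs of any black-box binary alarm model
    (for example an epileptic-seizure predictor running on EEG) so that its
    false alarm rate is statistically controlled at a user-chosen level.
    Implements a time-series adaptation of Learn-Then-Test calibration: a
    lambda-parameterised temporal aggregation (causal majority vote followed
    by optional max-pooling), central-limit-theorem p-values for the per-lambda
    risk hypotheses, and familywise-error-rate controlling selection via
    Bonferroni or fixed-sequence testing. Ships a synthetic generator of
    sparse event-window label series with a noisy-oracle predictor for
    validation studies, clinically tailored alarm metrics (event-based
    sensitivity, false alarms per non-preictal hour), and an optional EEG
    front end (EDF ingestion, FIR bandpass filtering, windowed spectral and
    nonlinear feature extraction, preictal labelling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
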