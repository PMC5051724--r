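Package: accelcut
Title: Sedentary Versus Light-Activity Cut-Points from Raw Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the ENMO (Euclidean Norm Minus One) and MAD (Mean
    Amplitude Deviation) intensity metrics from raw tri-axial accelerometer
    signals over fixed epochs, and derives and internally validates
    intensity thresholds that separate sedentary behaviours from common
    light-intensity physical activities. Includes a gravity-sphere
    auto-calibration stage, activity-log joining with transition trimming,
    univariate logistic regression with ROC-based threshold selection
    (Youden index), AUROC with DeLong confidence intervals, leave-one-out
    cross-validated AUROC, brand comparisons by unpaired t-tests, and a
    synthetic raw-signal generator that emulates a laboratory protocol of
    16 activities recorded at 100 Hz on hip- and wrist-worn devices of two
    brands.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    pROC,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
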