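Package: sensecast
Title: Steady-State Forecasting for Adsorptive Gas-Sensor Transients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the transient response of adsorptive (metal-oxide
    semiconductor and electrochemical) gas sensors with a family of
    exponential and stretched-exponential (Kohlrausch) response models
    rooted in Langmuir adsorption kinetics, and forecasts the steady-state
    (final) sensor value from a short initial window of the transient.
    Provides a signal pipeline for raw acquisition channels (ADC counts,
    voltage-divider resistance, shunt-amplifier current, median filtering,
    airflow-based exposure-onset detection), multi-start nonlinear
    least-squares fitting and model comparison, a synthetic exposure
    generator with split-then-augment dataset construction, two small
    multilayer-perceptron forecasters trained with Adam, and
    outlier-robust evaluation via arithmetic and geometric mean absolute
    (percentage) errors.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
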