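Package: ozimpact
Title: Climate-Driven Ozone Change and Mortality Impact Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the mortality burden of climate-driven
    changes in ground-level ozone. Implements a Bayesian space-time model
    linking daily maximum 8-hour average ozone to weather with a separable
    exponential residual covariance, regression calibration of climate-model
    weather output, multi-community quasi-Poisson time-series mortality
    models with unconstrained distributed lags, two-level normal hierarchical
    pooling of community relative risks, and attributable-deaths estimation
    with delta-method uncertainty. Includes a seeded synthetic-data generator
    with recorded ground truth so the full pipeline can be exercised and
    validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
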