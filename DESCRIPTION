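Package: boostjm
Title: Likelihood-Based Boosting for Joint Models of Longitudinal and
    Time-to-Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits joint models coupling a Gaussian longitudinal outcome with a
    right-censored time-to-event outcome by component-wise likelihood-based
    boosting. The survival submodel uses a full likelihood with a
    piecewise-constant baseline hazard, the longitudinal submodel is a linear
    mixed model with correlated random intercepts and slopes, and the two are
    linked through the current value of the longitudinal trajectory scaled by
    an association parameter. Early stopping of the component-wise updates
    yields regularized estimates and implicit variable selection in both
    submodels; the stopping iterations are tuned by cross-validated joint
    likelihood. Includes a two-stage variant where the longitudinal submodel
    is fitted by maximum likelihood, and a synthetic-data generator producing
    joint data via inversion sampling of event times under the assumed hazard.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
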