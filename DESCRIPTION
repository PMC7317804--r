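Package: jointtraj
Title: Joint Modelling of Longitudinal D-Dimer Trajectories and Time to
    Venous Thromboembolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic assessment of venous thromboembolism (VTE) risk in
    cancer patients from longitudinal D-dimer measurements. Implements a
    maximum-likelihood joint model coupling a random-intercept-and-slope
    mixed model for the biomarker trajectory with a Weibull
    proportional-hazards submodel for time to VTE, linked through a
    current-value (optionally first-derivative) association parameter and
    integrated by pseudo-adaptive Gauss-Hermite quadrature. Also provides
    competing-risk cumulative incidence (Aalen-Johansen), Kaplan-Meier,
    baseline Weibull proportional-hazards regression, individualized
    dynamic risk prediction conditional on a patient's biomarker history,
    and a synthetic-cohort generator emulating monthly-visit oncology
    cohorts for end-to-end testing and calibration studies.
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
    jsonlite,
    lme4,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
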