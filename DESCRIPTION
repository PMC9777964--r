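Package: hpavv
Title: Verification and Validation of HPA Axis Differential-Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A verification-and-validation workbench for differential-equation
    models of the hypothalamic-pituitary-adrenal (HPA) axis. Provides an
    adaptive Runge-Kutta integrator with continuous dense output and
    method-of-steps support for delay differential equations, a plugin
    contract for model definitions with three demonstration HPA models,
    a spline-interpolated mean-normalized cost function for comparing
    simulated ACTH and cortisol against stress-test data, a seeded
    differential-evolution calibration harness with repeated-run and
    multi-subject validation protocols, generalization testing across
    subjects, and synthetic generators for Trier Social Stress Test (TSST)
    cohorts and 24-hour basal hormone series.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
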