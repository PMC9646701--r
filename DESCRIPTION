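Package: eyeblinkr
Title: Simulation and Analysis of Eyeblink Conditioning and Motor-Battery Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for delay eyeblink conditioning and companion
    motor tasks in mice. Simulates seeded cohorts of eyelid-position traces
    with the standard session structure (20 blocks of 1 CS-only, 1 US-only and
    10 paired trials; interstimulus-interval switch from 250 to 500 ms at day
    11), scores traces (zero-phase Butterworth filtering, interquartile-range
    trial validity, unconditioned-response-referenced normalization to
    normalized eye closure units, conditioned-response detection and timing
    metrics), fits the multilevel statistical battery (mixed binomial
    logistic, linear mixed, mixed beta, and Cox frailty models with
    likelihood-ratio or Wald omnibus tests and Holm-corrected per-day
    contrasts), and analyses ladder, rotarod, balance-beam and grip-strength
    tables, including the two-part clean-sweep analysis and censored-latency
    preparation.
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
    glmmTMB,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
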