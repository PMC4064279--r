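Package: injurydesign
Title: Design Toolkit for Daily Psychological-State Injury Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning tools for prospective studies of daily psychological
    states as predictors of performance injuries in athlete and performing-
    artist cohorts. Provides a synthetic generator for correlated daily
    ordinal state panels and rare injury processes, one-way ANOVA intraclass
    correlation estimation for unbalanced panels, Monte-Carlo power for
    marginal (GEE-type) and mixed-model analyses of daily-measurement
    designs, closed-form sample size for m:1 matched case-control and
    case-crossover designs with correlated dichotomous exposure, study
    duration planning, and injury incidence-rate descriptives.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
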