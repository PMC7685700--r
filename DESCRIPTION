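Package: phenoshift
Title: Longitudinal Behavioral Shift Analysis of Search and Watch Activity Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying longitudinal shifts in individual online
    behavior from timestamped search and video-watch activity logs across a
    pre/post event boundary, and for relating those shifts to changes in
    PHQ-9 depression and GAD-7 anxiety screening scores. Implements circadian
    hourly activity profiles with relative-change analysis, bedtime proxies
    from last nightly activity, session thresholds estimated from two-component
    mixtures of log inter-event gaps, pluggable stem-lexicon word counting and
    rule-based category annotation, Pearson correlation batteries with Fisher-z
    confidence intervals, paired seasonal-slope tests, and leave-one-out
    evaluation of ordinary and L1-penalized regression. A seeded synthetic
    cohort generator with a ground-truth ledger lets the full analysis run with
    no real user data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lubridate,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
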