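# phenoshift

Quantifies longitudinal shifts in individual online behavior from
timestamped search and video-watch activity logs across a pre/post event
boundary, and relates those shifts to changes in PHQ-9 depression and GAD-7
anxiety screening scores. It is aimed at digital-phenotyping and
mental-health researchers who have (or want to prototype against)
per-participant activity histories plus two-wave screening surveys.

## What it computes

For each participant, events are split into a *before* window, an excluded
transition buffer, and an *after* window (defaults
`[2020-01-01, 2020-03-01)` / `[2020-03-01, 2020-03-29)` /
`[2020-03-29, 2020-06-01)`, local clock time). Every behavioral shift is a
relative change

&nbsp;&nbsp;&nbsp;&nbsp;Δ = (after − before) / before × 100

applied to five feature families:

* **Hourly activity distributions** — 24-bin local-hour profiles
  (events/day), changed per hour: Δ<sub>h</sub> for h = 0…23.
* **Last-seen activities** — a bedtime proxy: the shift (hours) of the
  median last nightly event before cutoffs at midnight–5 AM, with nights
  encoded on a continuous scale across midnight (1:30 AM → 25.5).
* **Short event intervals (SEIs)** — counts of same-platform gaps below a
  session threshold τ, estimated per platform as the equal-responsibility
  crossing of a two-component Gaussian mixture fitted by EM to log₁₀
  inter-event gaps.
* **Lexicon word counts** — dimension-wise word counts from a pluggable
  stem lexicon (`.dic` or YAML), scored separately for search queries and
  video titles, plus generic weighted summary-score hooks.
* **Category volumes** — rule-based (keywords + URL domains) counts for
  `adult` and `news` content.

Statistics: Pearson correlation batteries of every feature cell against
Δ PHQ-9 and Δ GAD-7 with Fisher-z 95% CIs; paired t-tests of within-year
seasonal slopes (S₂₀₂₀ vs S₂₀₁₉); leave-one-out evaluation of OLS and lasso
regressions on a 6-dim temporal and a 9-dim semantic feature vector,
reporting per-split squared errors, mean MSE, pooled-prediction
R² = 1 − PRESS/SST, and full-data coefficient tables.

A seeded **synthetic cohort generator** (session-structured event streams,
circadian placement, injectable bedtime delays, burstiness and topic
shifts, and survey scores linked to features at chosen target correlations)
with a ground-truth ledger lets the whole pipeline run and be tested with
no real user data. See the methods vignette
(`vignettes/behavioral-shift-pipeline.Rmd`) for the model and every design
decision.

## Worked example

```r
library(phenoshift)

co <- generate_cohort(cohort_config(n_participants = 30, seed = 1,
                                    profile = behavior_profile(daily_rate = 40)))
co$taus
#> google_search       youtube
#>         269.0         257.8

battery <- correlation_battery(co$features, co$survey)
dplyr::filter(battery, feature_name == "hourly_change",
              parameter %in% c("2", "3", "4"), score == "delta_phq9")
#>   feature_name  parameter score          r ci_low ci_high    p_value     n significant
#> 1 hourly_change 2         delta_phq9 0.550  0.236   0.759 0.00166       30 TRUE
#> 2 hourly_change 3         delta_phq9 0.734  0.508   0.865 0.00000396    30 TRUE
#> 3 hourly_change 4         delta_phq9 0.475  0.139   0.713 0.00798       30 TRUE

X  <- build_feature_matrix(co$features, feature_vector_spec("temporal"))
sv <- co$survey[match(rownames(X), co$survey$participant_id), ]
glance(loo_evaluate(X, sv$delta_phq9, model_config("lasso"), target = "delta_phq9"))
#>   model  alpha     n   mse    r2 target
#> 1 lasso 0.0001    30  10.4 0.459 delta_phq9
```

Reading the output: the fitted session thresholds land in the minutes range
for both platforms (consecutive consumption); the correlation battery
recovers the injected late-night signal — the 3 AM activity change is the
strongest hourly correlate of the PHQ-9 delta (r = 0.73, 95% CI 0.51–0.87),
flanked by weaker 2 AM and 4 AM correlations; and the temporal feature
vector predicts the score change under leave-one-out with pooled R² = 0.46
(the semantic vector, which carries no injected signal in this default
cohort, does not: R² = −0.06). The cohort's `ledger` records every injected
ground-truth parameter for exactly this kind of verification.

A full pipeline run (simulate → features → correlations → models →
reports) from one config file:

```r
run_pipeline(system.file("extdata", "demo_config.yml", package = "phenoshift"),
             out_dir = "demo_out")
```

or from a shell via the thin CLI wrapper
`inst/cli/phenoshift.R` (`run`, `simulate`, `extract`, `correlate`,
`model` subcommands).

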