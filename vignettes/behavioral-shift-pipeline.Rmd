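---
title: "Quantifying behavioral shifts in activity logs and relating them to mental-health score changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral shifts in activity logs and relating them to mental-health score changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoshift)
```

## The problem

phenoshift implements a digital-phenotyping analysis for longitudinal,
individual-level search and video-watch activity logs observed across a
sharp event boundary (the motivating case is a pre/post-lockdown design:
a January–February baseline window, a buffer around the transition, and a
late-March–May follow-up window). Each participant also completes the PHQ-9
depression and GAD-7 anxiety screeners at both waves. The analysis asks: do
quantifiable shifts in how a person uses these platforms — when they are
active, how late their last nightly activity falls, how bursty their
consumption is, and what they search for and watch — correlate with, and
predict, the change in their screening scores?

Because real activity logs of this kind are private and cannot be
redistributed, the package ships a first-class synthetic cohort generator
with a ground-truth ledger. Every downstream stage — windowing, feature
extraction, correlation batteries, leave-one-out regression, descriptive
reports — runs identically on real logs in the documented JSONL/CSV schema
and on synthetic cohorts, and the ledger makes every injected effect a
recoverable target for testing.

## Analysis windows and the universal shift measure

All features are computed per participant in two half-open calendar windows
(`[2020-01-01, 2020-03-01)` and `[2020-03-29, 2020-06-01)` by default) with
the four weeks in between excluded, so acute transition behavior
contaminates neither side. Temporal semantics are local wall-clock time: a
"3 AM" bin means 3 AM on the participant's clock, which is the scale on
which late-night behavior is meaningful. Timestamps are stored with explicit
UTC offsets and converted for analysis.

Every feature-level change is the relative change

$$\Delta = \frac{\text{after} - \text{before}}{\text{before}} \times 100,$$

implemented once in `relative_change()` and reused by every module. A zero
baseline makes the ratio undefined; the `zero_policy` argument either drops
the cell (`"strict"`, the analysis default, with pairwise deletion and a
logged n downstream) or substitutes one event-equivalent for the zero
baseline (`"pseudo"`), which keeps rare behaviors in play at the cost of a
scale assumption. The synthetic generator uses `"pseudo"` internally when
linking scores so that sparse night-hour cells cannot produce missing link
features.

## Temporal features

**Hourly activity profiles.** `hourly_histogram()` tallies events into 24
local-hour bins; profiles are normalized to events/day by default because
the two windows have unequal lengths (60 vs 64 days). A raw-count mode
reproduces the cumulative-count construction exactly.
`hourly_relative_change()` then gives 24 per-hour change percentages per
participant.

**Last-seen activity.** `last_seen_times()` implements a bedtime proxy: for
each night (anchored at 18:00 local, configurable — the anchor is a design
choice, since only the cutoffs are prescribed), the last event before a
cutoff hour `T` in {midnight, 1 AM, …, 5 AM}. Times are encoded as
continuous hours since the night's midnight (1:30 AM next day is 25.5) so
medians are meaningful across midnight. `last_seen_shift()` is the
difference of the per-window medians; +1.5 means the typical last activity
moved 1.5 h later. The encoding is monotone in clock time, so a pure
translation of the night-time event stream shifts the estimate by exactly
the translation.

**Short event intervals (SEIs).** An SEI is an inter-event gap below the
platform's session threshold — consecutive consumption within one session.
The threshold is not hand-picked: `fit_gap_mixture()` fits a two-component
Gaussian mixture to pooled log10 inter-event gaps per platform by EM and
takes the equal-responsibility crossing between the component means as the
boundary between in-session and between-session gaps. The
equal-responsibility criterion (rather than equal density) stays well
defined when mixing weights are unequal. Numerical choices: exact 1-D
two-means initialization (deterministic, so refits are byte-identical),
log-likelihood tolerance 1e-6, at most 500 iterations, hard errors on
degenerate variance or vanishing components; the crossing is found by root
bisection between the component means. Gaps are always formed within one
participant and one window, so no gap spans the excluded buffer. Pooling is
per platform across the cohort (one threshold per platform, matching the
search-versus-video session-scale distinction); thresholds of very
different orders — an hour-scale search boundary versus a minutes-scale
video boundary — are purely a property of the data, not of code paths.

## Semantic features

**Lexicon word counts.** `lexicon_counts()` is a transparent word-count
engine over a pluggable stem lexicon: a dimension matches a token if the
token equals a literal pattern or begins with a `stem*` prefix; one token
may feed several dimensions. The package reads the classic `%`-delimited
`.dic` dictionary layout and a YAML dialect. The bundled lexicon is
synthetic — small hand-picked stem lists for work, money, death, anxiety,
sadness, friends, positive/negative emotion and first-person language — it
reproduces the mechanism of commercial psycholinguistic dictionaries
without redistributing one, and no fidelity to any proprietary dictionary's
coverage is claimed. Search queries and video titles are scored as separate
streams, since their language differs. Composite "summary" scores
(authenticity-style, tone-style) are exposed as a generic weighted-sum hook
over dimension percents with caller-supplied weights; because such scores
can be negative, their shift feature is a score difference rather than a
relative change.

**Category volumes.** `categorize_events()` is a rule-based annotator:
keyword patterns on event text plus domain lists on URL hosts, multi-label
by design (counts are per-category volumes, not a partition). The default
rules cover `adult` and `news`; `adult` is computed from the search
platform's events by convention. This replaces commercial classification
APIs with auditable rules; the labels are not claimed to replicate any
proprietary taxonomy.

## Statistics

`pearson_with_ci()` reports the product-moment correlation with a two-tailed
p-value from the t transform (n − 2 df) and a 95% CI from the Fisher z
transform. `correlation_battery()` sweeps all (feature, parameter, score)
cells — 24 hours × 2 scores, 6 cutoffs × 2, per-platform SEIs × 2, lexicon
dimensions and categories — with pairwise deletion and a reported n per
cell; cells with fewer than 4 complete pairs become missing rows. Raw
p-values are reported by default to mirror the per-cell testing convention;
Benjamini–Hochberg adjustment is available behind a flag.

The seasonal control compares within-year slopes: for each participant and
year, the before-window and after-window feature values are joined by a line
whose x-coordinates are the window midpoints (the construction needs
comparable spacing across years; midpoints are the natural choice when
nothing else is prescribed), and `paired_slope_test()` applies a two-tailed
paired t-test to the 2020-vs-2019 slopes. The "paired independent" wording
in the source description is self-contradictory; the construction compares
two slopes within each participant, so the paired test is the coherent
reading, and all-zero differences are reported as t = 0, p = 1 flagged
degenerate rather than as errors.

## Predictive models

Two fixed feature vectors are evaluated: *temporal* (hourly changes at 2, 3,
4 AM; last-seen shifts at the 4 and 5 AM cutoffs; short video intervals; 6
dimensions) and *semantic* (work/money/death/authentic-hook from search,
anxiety/sadness/friends/tone-hook from video, adult category; 9 dimensions).
`build_feature_matrix()` imputes sporadic missing cells with the column
median (cohorts of ~50 cannot afford listwise deletion) and errors on
components absent for everyone.

`loo_evaluate()` runs the n-fold leave-one-out protocol with predictors
standardized inside each training fold only, so the held-out point never
influences its own fold. The penalty for the L1 model defaults to a fixed
alpha of 1e-4 on the `1/(2n)·RSS + alpha·||b||_1` scale (reproducibility);
inner-loop tuning over a grid, by a complete leave-one-out within each
training fold, is available behind a flag. Reported metrics are the mean of
the per-split squared errors (MSE) and the pooled-prediction
R² = 1 − PRESS/SST over all held-out predictions — a per-split R² on a
single test point is undefined, so an "average R²" is reported in this
pooled form and labelled as such. Coefficient tables come from one
full-data fit on standardized predictors (averaging fold coefficients is
the other defensible choice; the full-data fit is the one reported, and it
is stated with the table).

## The synthetic cohort generator

`generate_participant()` simulates a session-structured event stream rather
than a plain Poisson process, so the SEI mixture structure exists by
construction: the number of events in a window is Poisson with mean
`daily_rate × days`; events are partitioned into sessions with geometric
lengths (mean `1/p`); sessions start at hours drawn from a 24-bin circadian
weight vector (uniform within the hour) and fill with lognormal
within-session gaps. Between-session gaps arise from session placement, and
the profile's between-session log-gap parameters record that regime; the
ground-truth session boundary in the ledger is the equal-responsibility
crossing of the configured in-session and between-session components with
in-session weight `1 − p`.

The defaults are chosen to emulate the motivating cohort: 85 events/day
(matching ~2400 searches plus ~2900 watches per two-month window), 55%
video-platform share, an evening-heavy circadian profile that peaks near
midnight, falls sharply after 1 AM and bottoms out before dawn (the sharp
night edge is what makes a bedtime proxy from last nightly events
well-concentrated over a 60-night window), 20-second median in-session gaps,
and a ~1-hour-scale between-session regime.

The bedtime shift is implemented as an exact circular rotation of the
night-time (22:00–06:00) intensity: session starts in the night arc move
`delta` hours later, continuously, wrapping within the arc, while daytime
mass stays in place. This matches the delayed-bedtime pattern the temporal
features are designed to detect without changing total volume, and because
it is a true translation of the night intensity, the last-seen median shift
recovers the injected `delta` up to sampling noise (within ±0.25 h on
60-night windows at the default volume — a property the test suite checks
against the ledger).

`link_scores()` makes score deltas a linear combination of the standardized
shift features with loadings equal to the target correlations plus Gaussian
noise scaled to `sqrt(1 − sum(rho²))`, so each target correlation is met in
population for uncorrelated features (correlated features induce `R rho`,
slightly above target); requests with `sum(rho²) > 1` are rejected as
infeasible. Integer scores are then formed by rounding and clipping to the
instrument ranges (0–27, 0–21) and deltas recomputed, which adds a small,
quantified attenuation; a continuous-score mode preserves the exact linear
link for calibration studies (with a single feature at rho = 1 it yields a
sample correlation of exactly 1) and is also the regime in which the
lasso's exact zeroing of no-signal features is a theorem rather than a
tendency — the modeling sanity checks use it for that reason.

`generate_cohort()` draws per-participant injected shifts (bedtime delay
~N(0.75 h, 0.6 h) clipped to [−0.5, 2.25]; mild lognormal volume and
burstiness multipliers; lognormal category-weight multipliers on the
emotionally loaded pools), generates all logs, fits the pooled thresholds
and extracts the feature table with the package's own pipeline, links the
surveys, and records everything injected in the ledger before noise.
All randomness descends from one integer seed through per-participant
derived seeds; nothing touches the global RNG state, and a serialized
configuration regenerates a byte-identical cohort.

What the generator does **not** emulate: realistic query language (tokens
are drawn from small topical pools), platform-specific gap regimes (one gap
regime serves both platforms by default; the search-hour/video-minutes
distinction is available through configuration), event-boundary content
drift beyond category-weight changes, demographic effects on behavior, and
any year-specific content. A previous-year replay for the seasonal control
is a configuration choice (windows shifted by one year, no injected shift),
not an inference about what earlier behavior looked like. Passing tests on
synthetic cohorts therefore validate the machinery and its calibration,
not any empirical claim about real populations.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at deliberately modest scale —
cohorts of 6–30 participants at 12–40 events/day for integration tests, one
participant at the default 85 events/day for bedtime-shift recovery, 2,000
gaps for threshold recovery, n = 200 with 100 replicates for link
calibration, 200 replicates for the null calibration of the paired slope
test, and a 14-participant demo pipeline run twice for byte-identical
determinism. These sizes keep the whole suite fast while leaving every
statistical check adequately powered; nothing in the methodology depends on
them.

## Known limitations

* Percentage change is asymmetric and unbounded near zero baselines; the
  strict policy plus pairwise deletion is the honest default, but cells with
  many zero baselines (rare behaviors, sparse hours) lose n.
* The equal-responsibility threshold assumes the two-component mixture is an
  adequate description of the log-gap distribution; heavy middle mass
  between regimes will move the crossing.
* With correlated features the score link overshoots targets slightly
  (`R rho` vs `rho`); the calibration tests use single-feature injections
  where the two coincide.
* Integer rounding of survey scores attenuates injected correlations by a
  known, small factor; exactness claims hold for the continuous latent link.
* The rule-based category annotator and the synthetic lexicon are
  transparent mechanisms, not replications of any commercial taxonomy or
  dictionary; absolute category/dimension volumes are not comparable to
  those tools' output.

## A short worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_config(n_participants = 12, seed = 1,
                                    profile = behavior_profile(daily_rate = 40)))
co$taus                               # fitted per-platform session thresholds
battery <- correlation_battery(co$features, co$survey)
dplyr::filter(battery, feature_name == "hourly_change", significant)

X <- build_feature_matrix(co$features, feature_vector_spec("temporal"))
sv <- co$survey[match(rownames(X), co$survey$participant_id), ]
glance(loo_evaluate(X, sv$delta_phq9, model_config("lasso"), target = "delta_phq9"))
```
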