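---
title: "Models and methods behind srttci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srttci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srttci)
```

## The study family this package serves

`srttci` implements the complete computational apparatus of a two-day serial
reaction time task (SRTT) study of contextual interference. Participants
respond with four fingers (keys U, I, O, P) to cued locations; unknown to
them, the cues follow three eight-item sequences, each containing every key
exactly twice. On Day 1 (training) the 240 trials present each sequence 80
times, either *blocked* (AAA...BBB...CCC) or *interleaved* (ACBABCBAC...);
on Day 2 (testing) the same happens with either the same sequences
(retention design) or three novel ones (transfer design), crossing training
and testing conditions into four cells: BB, II, BI and IB. After Day 2 a
free-recall questionnaire probes explicit sequence knowledge, and a Monte
Carlo calibration of chance recall sorts participants into implicit and
explicit learners.

The package covers five concerns: experimental-design generation
(`build_experiment_design()`), a synthetic-participant generator
(`simulate_cohort()`), recall scoring and chance calibration
(`score_recall()`, `calibrate_chance()`, `classify_learner()`), windowed
difference-score metrics (`sequence_rts()`, `window_mean()`,
`difference_scores()`), and the statistical battery (`mann_kendall()`,
`factorial_anova()`, `ancova()`, `mann_whitney_u()`, t tests,
`tukey_posthoc()`), orchestrated end to end by `run_experiment()`.

## Design generation

A valid sequence is a permutation of the multiset {U,U,I,I,O,O,P,P}; there
are 8!/2^4 = 2520 of them (`all_sequences()` enumerates the space).
`generate_sequence()` samples uniformly, optionally excluding a forbidden
set, so that no two participants receive the same ordered set of sequences.

Interleaved trial orders are drawn under a run-length cap (default 2): no
more than two identical adjacent labels, keeping interference high
throughout the session. A rejection-sampled full shuffle of an 80/80/80
multiset essentially never satisfies such a cap (a random shuffle contains
on the order of two dozen runs of length three), so the sampler builds the
order sequentially, choosing each trial's label among those with remaining
presentations - excluding the current label once the cap is reached -
weighted by remaining counts, and restarting on the rare dead end. This
realizes the same constraint set with uniform-ish coverage and bounded
runtime; the cap is configurable (`run_cap`).

Other free choices, fixed once: the order of the three blocks in a blocked
day is randomized per participant per day; no adjacency constraint is
placed on keys within or across sequences by default (an optional flag
forbids immediate key repeats within a sequence); the stimulus stream
carries no sequence-boundary markers (participants are never told sequences
exist) - boundaries exist only in schedule metadata. "No two participants
share the same sequences" is interpreted as no shared *ordered set*;
individual sequences may recur across participants when the space is tight.

## The generative model of a synthetic participant

No trial-level human data are deposited for this paradigm, so every
downstream stage is exercised against a generative stand-in whose defaults
encode the study conditions. The per-press reaction time is

$$
rt = \max\!\big(rt_{floor},\; \beta
  + G\,e^{-t/\tau_G}
  + S\,e^{-e/\tau_S}
  + c_{sw}\,[\text{switch}]
  + \mathcal{N}(0, \sigma)\big),
$$

with `t` the cumulative trial index across both days, `e` the number of
prior exposures of the trial's sequence within its learning phase, a switch
cost when the sequence changes between consecutive trials, and a Day-2
consolidation offset added to the base. Responses are correct with
probability `1 - press_error_prob` (condition-dependent), otherwise a
uniformly wrong key. This is the minimal parameterization that can realize
every qualitative phenomenon the analysis battery is sensitive to:
monotone RT speed-up over 240 trials, faster blocked acquisition, the
switch cost and higher error rate under interleaving, overnight offsets by
condition, and recall graded from chance to perfect via `explicit_k`
(the number of leading items per sequence available to recall).

Parameter defaults (seconds): base 0.35 per press, floor 0.15 (truncation,
not resampling), noise SD 0.05, nonspecific gain 0.04 with tau 80 trials,
sequence-specific gain 0.10 with tau 30 exposures under blocked practice
and 400 under interleaved (sequence-specific learning is slower under high
interference, which is what makes blocked Day-1 acquisition faster), switch
cost 0.06. Per-press error rates are ~5.5% (blocked) vs ~7.5% (interleaved)
in the retention preset, giving day accuracies in the 92-96% range.

Three shipped presets map group assignment to participant parameters,
drawing modest between-participant heterogeneity around these means:

* **null** - no condition effects at all (no switch cost, equal error rates
  and learning rates, zero-mean consolidation offsets). Retention scores
  are then exchangeable across cells, so the downstream ANOVA's rejection
  rate calibrates the pipeline's type-I error.
* **paper-like** (retention) - Day-2 consolidation offsets are
  cell-specific, bundling overnight consolidation with how well the trained
  mode of responding carries into the test schedule: II -0.04 and IB 0.00
  s/press (interleaved training is insensitive to testing condition), BB
  +0.02 (blocked training barely holds under blocked testing) and BI +0.10
  (strong impairment under interleaved testing, on top of the switch costs
  BI's Day-2 window uniquely pays while its Day-1 window did not). With 20
  participants per cell this yields cell retention means of roughly +0.13
  (BB), +1.0 (BI), -0.26 (IB) and -0.27 (II) seconds. Recall ability
  `explicit_k` is drawn higher for blocked-trained participants,
  calibrated so *measured* items-per-sequence (explicit knowledge plus
  chance credit) averages about 4.2 (blocked) vs 3.2 (interleaved) and the
  implicit/explicit split is roughly balanced.
* **transfer-like** - Day-2 carry-over offsets are again cell-specific
  (BB -0.055, II -0.020, IB 0.000, BI -0.045 s/press; the offsets combine
  with the cell's window asymmetries in switch costs and learning terms so
  the *net* transfer scores land near the pattern of interest), and BI
  additionally has its Day-2 sequence-learning *rate* scaled to zero, so
  its novel sequences start at naive level and stay flat. Scaling the rate
  rather than the gain is deliberate: removing the gain would make Day 2
  *faster* (the decaying slowness term would vanish), the opposite of an
  unprepared learner. The preset produces clearly negative transfer scores
  in BB/II/IB (about -0.5, -0.4 and -0.7 s), a near-zero BI score, and a
  non-significant BI Day-2 trend while the other cells show significant
  decreasing trends.

Recall simulation reproduces the first `explicit_k` items of each relevant
sequence followed by a random valid completion of the remaining key
multiset (`explicit_k = 0` gives fully random valid-format strings).
Transfer participants type strings based on their Day-2 (most recent)
sequences; their scores are computed against all six truths. Errors are
independent across presses; post-error slowing is off by default but
available (`post_error_cost`).

What the generator does *not* emulate: RT autocorrelation and fatigue
drifts, post-error slowing by default, heavy-tailed RT distributions,
individual learning-rate/explicitness correlations, and any real-data
magnitudes beyond the sign patterns above - preset parameters are
calibrated to the qualitative patterns, not fitted to data. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes,
not that real data obey the model.

## Recall scoring and the chance calibration

The similarity between a typed string and a true sequence is, by default,
the fraction of the eight positions at which they agree (denominator always
8; shorter strings earn credit only on covered positions, characters past
the eighth are ignored). This *positional* rule is the package default
because it reproduces the analytic chance level the classification is
anchored to: two independent uniform valid sequences agree at each position
with probability $\sum_k (2/8)^2 \cdot 4 = 0.25$, i.e. two items per
sequence. A stricter `longest_run` rule (longest contiguous match run / 8)
is provided as an alternative; how "sequential items" were operationalized
originally is not defined, so both are exposed.

`score_recall()` matches typed strings to truths by a one-to-one assignment
maximizing total similarity (exhaustive for the small instances that occur,
greedy beyond), so one typed string can never credit several truths;
unmatched truths score zero. The mean matched fraction times 8 is
items-per-sequence. In the transfer design six truths are probed; the mean
is taken over the best-matching three so the construct remains items *per
sequence* on the same scale as retention, and this choice is recorded in
the score object. `classify_learner()` labels a participant implicit when
items-per-sequence is below `cutoff_items + 1` (default: below 4, i.e. 0-3
items at or near chance; 4 or more is explicit).

`calibrate_chance()` replicates the chance experiment: each replicate draws
three fresh test sequences, computes each one's mean similarity over a
large random comparison set, and averages the three. At the package's
scaled defaults (10^4 comparison sequences, 500 replicates - chosen so the
full calibration runs in seconds while the replicate means still have
standard error below 0.001) the replicate means concentrate tightly around
0.25; the band is reported as an envelope (min, max) and checked for
containment in [0.23, 0.26]. The reference experiment's much wider spread
at 10^6 comparisons per replicate is wider than sampling error under any
per-position rule, so the package reports its own band and checks
containment only. An `exhaustive = TRUE` mode replaces the random
comparison set by the full 2520-sequence space, making each replicate mean
exactly 0.25 under the positional rule - the analytic anchor used in the
tests.

## Metrics

Sequence RT is the sum of the eight press RTs; only fully correct trials
enter the analysis windows (error trials are retained in the record but
skipped when filling windows, so "last ten" means the last ten *correct*
trials; with fewer correct trials than the window requests, all available
are used with a warning). Under a blocked schedule a window holds the
first/last 10 correct trials of each sequence (30 total); under an
interleaved schedule the first/last 30 correct trials regardless of label.
In mixed designs each day's window follows that day's own schedule
condition, since the schedule defines what "per sequence" means that day.

Difference scores (seconds; negative = faster):

* learning = mean(last window Day 1) - mean(first window Day 1)
* retention = mean(first window Day 2) - mean(last window Day 1)
* transfer = mean(first window Day 2) - mean(first window Day 1)

Zero retention means perfect retention; positive retention means
forgetting. Accuracy is per key press (the 92-96% figures), with
per-sequence accuracy also emitted; participants below 80% on either day
are excluded before analysis.

## Statistical battery

`mann_kendall()` is implemented directly (S, tie-corrected tau and
variance, continuity-corrected normal approximation) and cross-checked in
the tests against exhaustive pair counting and `cor.test`. Group trend
tests run on the cell-averaged correct-trial RT series per trial index.
t tests and the Mann-Whitney U wrap the base R implementations (pooled
variance for the independent t; normal approximation with tie correction
for U), with Cohen's d reported from the pooled or sample SD. Factorial
ANOVA and ANCOVA use Type III sums of squares with sum-to-zero effect
coding via `car::Anova` - the convention appropriate for the unbalanced
cells that post hoc learner sorting produces (Type II is available by
flag); both classical and partial eta squared are emitted since reports in
this literature rarely say which is meant. Simple effects are one-way
ANOVAs within each level of the stratifying factor, using that level's own
error term (error-term pooling across levels is underdetermined in typical
reports; the within-level choice is documented here). Tukey-Kramer
post hoc comparisons collapse the design to a single cell factor. Exact
small-sample null distributions for U and tau are out of scope; the normal
approximations are used throughout, two-sided.

The independent oracles for all of these live in the test suite: brute-force
pair counting for S and U, hand-solved normal equations for the Type III
decomposition on a 12-row fixture, textbook one-way arithmetic for simple
effects, and exhaustive pairing for the recall assignment.

## The experiment runner

`run_experiment()` wires the stages together under a single seed:
simulate (or ingest) -> metrics -> exclusions -> recall scoring -> trend
tables -> battery. Retention runs fit the 2x2x2
(training x testing x learner) ANOVA, the testing-within-training and
learner-within-training simple effects, and the 2x2 ANCOVA with recall
score as covariate; transfer runs fit the 2x2 ANOVA, Tukey-Kramer
comparisons and the ANCOVA, plus per-cell Day-2 trend tests. Per-cell
one-sample t tests, the accuracy Mann-Whitney comparisons and the recall
t test run in both designs. Any test that cannot be computed on a given
cohort (an empty learner cell, say) is recorded as an error object rather
than aborting the run. With `out_dir` set, every stage artifact is
materialized (CSV/JSON) so stages can be inspected or re-run in isolation.
An unreachable accuracy threshold yields an empty analysis with an
explicit notice rather than an error.

## Numerical choices and degenerate inputs

* RT truncation at the floor (0.15 s) rather than resampling.
* All-tied series: Mann-Kendall returns tau 0, p 1. Zero-variance samples
  make the t tests fail loudly rather than return NaN.
* Empty typed recall scores zero; invalid characters are dropped with a
  warning; strings shorter or longer than 8 are compared over at most the
  first eight positions with denominator 8.
* Ties in the one-to-one recall assignment resolve arbitrarily among
  equal-total pairings; only the multiset of matched fractions is
  identifiable, and only means enter downstream analyses.
* The problem sizes used by the shipped checks (500 null replications at 15
  participants per cell; 100 pattern replications at 20 per cell; 10^4 x
  500 calibration) were chosen once as the smallest sizes at which the
  binomial/Monte Carlo error of the checked quantity is comfortably below
  the decision margin.

## Known limitations

The generator's effects are additive and Gaussian on the press scale;
nothing guarantees real SRTT data are. The chance band is an envelope, not
a distributional target. The implicit/explicit dichotomy inherits all the
caveats of free recall as an awareness measure. Sleep covariates,
handedness, stimulus presentation and neural measures are out of scope.
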