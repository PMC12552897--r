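---
title: "Methods: from minute-level bed-sensor streams to a sleep-disturbance index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from minute-level bed-sensor streams to a sleep-disturbance index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `drisleep`, the
assumptions they rest on, the parameters a user may want to change, and the
design decisions taken where more than one reasonable choice existed. The
running theme is longitudinal, contactless monitoring of night-time
behavior in older adults and people living with dementia: an under-mattress
pressure sensor emits one record per occupied minute, and everything the
package computes is derived from the presence, timing and content of those
records.

## 1. The nightly feature model

### Windows, periods, episodes

A *night* is a noon-to-noon window in the sleeper's local wall-clock time.
Noon is a natural cut because bed occupancy around midnight is the norm
while occupancy at midday is the exception; the convention also bounds a
night at 1440 minutes (1380/1500 on daylight-saving transition days, where
the grid follows elapsed wall-clock minutes). Sleep episodes longer than a
circadian cycle cannot occur under this convention by construction; such
episodes are usually linked to acute medical events and are outside the
package's scope.

Within a window, occupied minutes form *bed periods* (maximal runs of
consecutive observations, half-open `[start, end)`). Periods separated by
less than 30 minutes out of bed merge into *episodes*: a brief trip to the
bathroom does not end a night. The 30-minute threshold is strict — a gap of
exactly 30 minutes splits. An episode starting between 08:00 (inclusive)
and 20:00 (exclusive) and ending on the same calendar day is a *diurnal*
nap; all other episodes are *nocturnal*. When one window contains several
nocturnal episodes the one with the most observations is taken as the
night's principal episode; the paper-trail for the rare remainder is the
occupancy grid itself.

### Metrics

All nightly metrics are integer-minute arithmetic on the principal
nocturnal episode; timestamps are authoritative and clock angles
(15°/hour; bedtimes from a midday origin, arise times from midnight) are
derived from them, never the reverse. The printed-angle identity
`NOP = (ARISE + 180° − TO_BED)/15 (mod 360)` holds because the two angle
conventions differ by a 180° origin offset. `NOP` uses the inclusive span
(first to last observed minute plus one): a night observed from 22:00
through 06:59 spans 540 minutes, 9 hours. A *bed exit* is a timestamp gap
of at least 2 minutes, i.e. at least one fully absent minute; `EXIT_DUR`
is total absent time over the exit count and defined as 0 for exit-free
nights (the quotient is otherwise undefined, and a 0 trivially passes the
exit-duration filter). Missing heart-rate or respiration values within an
occupied minute do not affect occupancy — presence of the record, not of
the physiology, defines being in bed — but a night whose mean `HR`/`RR`
cannot be computed at all is dropped by the filter as having missing
values. `SNR` is snore minutes over occupied minutes, a ratio in `[0, 1]`
(the minutes/hours unit mismatch in the naive `SNT/IBT` form is resolved in
favor of the bounded ratio).

### Quality filter

The extreme-value filter is a pure per-night predicate (idempotent,
order-invariant) with inclusive bounds except where stated: at most 20
exits; `IBP` in `[0.6, 1.0]`; `HR` in `[45, 85]` beats/min; `RR` in
`[10, 25]` cycles/min; mean exit duration at most 60 min; `OBT` strictly
under 180 min; `IBT` in `[4, 16]` h; bedtime inside `[17:20, 03:00]`
(wrapped across midnight); wake-up inside `[02:40, 23:45]`. Each rejected
night carries the named rules it violated, so exclusion tables are
reconstructible. The intent is to focus analysis on subtle disturbances
rather than on extreme nights that would otherwise dominate every
comparison.

## 2. Distribution-level comparison

When one group has thousands of times more nights than another, two-sample
tests are overpowered and their p-values uninformative. Groups are instead
compared by the Hellinger distance between binned metric distributions,
`H(P,Q) = sqrt(0.5 * sum((sqrt(p_i) - sqrt(q_i))^2))`, a bounded `[0, 1]`
f-divergence that is insensitive to sample-size imbalance. Bins are
canonical per metric — 50 equal-width bins over the filter-admissible range,
integer bins for exit counts — so distances are comparable across analyses;
out-of-range values clip into the end bins rather than vanish. Timing
association uses the Fisher–Lee circular correlation (computed via an
O(n) complex-sum identity so bootstrap confidence intervals over 1000
resamples stay cheap); the coefficient choice is a convention, as "circular
statistics" alone does not pin one down. Case–control balancing uses
logistic propensity scores on age and sex with greedy nearest-neighbor
matching without replacement, up to 10 controls per case, cases processed
in stable id order and ties broken by control id — conventions chosen for
reproducibility where the procedure is otherwise underdetermined.

## 3. Bed-occupancy phenotypes

Each standard night collapses to 96 quarter-hour occupancy counts. The
night-to-night dissimilarity combines, with equal weight, the Jaccard
distance between binary *non*-occupancy masks (which states were empty)
and the Euclidean distance between the counts (how full the shared states
were); the two live on incommensurable scales, so each is min-max
normalized over the dataset before averaging, and the constants are kept so
later nights project consistently. Ward linkage is applied to this combined
dissimilarity directly — a deliberate reproduction of the source analysis's
unconventional pairing of Ward with a non-Euclidean measure — and the
number of clusters is the Davies–Bouldin minimum over K = 2..10. Labels are
renumbered by descending mean occupancy duration (ties: larger cluster
first, then original label) so "cluster 1" always means the longest-in-bed
phenotype regardless of linkage order.

The phenotype classifier is an additive boosted model — gradient boosting
restricted to depth-one trees, so the fit is additive in its seven features
(`IBT`, `TO_BED`, `ARISE`, `NOP`, `OBT`, `EXITS`, `EXIT_DUR`) and each
feature's shape function can be read off its stumps, the property that
makes explainable boosting machines inspectable. Validation is
leave-one-group-out with participants as groups: every fold holds out one
participant's entire night history, so reported macro precision, recall,
F1 and accuracy measure generalization to unseen people, not unseen nights
of known people. Folds whose training data lose a class are skipped with a
diagnostic rather than silently scored.

Clustering at the two higher levels — 90-day pre-assessment windows and
participants — operates on phenotype-proportion vectors, which are already
probability distributions, so the Hellinger distance applies without
binning (computed in the square-root embedding, where it is Euclidean up to
a constant). Windows use Ward linkage with Davies–Bouldin selection, for
consistency with the night level; participants use complete linkage with
silhouette selection over K = 2..8, and a maximum silhouette below 0.25 is
flagged as no substantial structure. Windows qualify only with at least 15
distinct labelled nights in the half-open `[date − 90 d, date)` interval.

Group effects on outcomes use Welch's heteroscedasticity-robust ANOVA
(delegated to `stats::oneway.test`, with a closed-form fallback under a
1e-12 variance floor when a group is degenerate), eta-squared effect sizes,
a classic Levene check (ANOVA on absolute deviations from group means),
Games–Howell pairwise comparisons (Welch t with studentized-range
calibration, Hedges g), and Bonferroni correction across the outcomes
tested in one invocation.

## 4. The sleep-disturbance index

The index is an averaged ensemble of the same additive boosted
architecture, fitted as a binary case-vs-control night classifier on the
full 20-metric nightly vector. Its training protocol is designed around two
leakage risks: information flowing from test participants, and information
flowing backward in time.

- *Multi-level split*: 10% of participants per class (rounded half-down)
  are withheld entirely (naive test); each remaining participant's final
  30 days form the horizon test; the rest is the training universe.
  Participants with 30 or fewer nights have no tail to spare and go wholly
  to training (logged).
- *Per member*: participants are bootstrap-resampled within class; each
  sampled participant's timeline is cut into 10 equal blocks and one night
  per block per pass is drawn at van der Corput positions (3 passes by
  default) — quasi-random temporal sampling that spreads exposure across
  the timeline while preserving order; the majority class is randomly
  under-sampled to parity; unsampled nights of sampled participants supply
  internal test/validation AUCs. The van der Corput scheme is the package's
  own concretization of an otherwise unspecified sampler, and is isolated
  behind one function so it can be swapped.
- *Merge*: the ensemble score is the arithmetic mean of member
  probabilities (calibrated scale, not logits), so a single member is the
  identity and adding a constant-0.5 member provably shrinks every score
  toward 0.5.

The dummy baseline trains the identical pipeline on label-shuffled copies
of the training universe, one dummy per member, and is reported as the
mean of per-member metrics. This follows the source protocol of parallel
per-iteration null models, and matters numerically: merging many random
score functions does not drive the merged AUC to 0.5 (averaging cancels
member noise but sharpens whatever small mean direction remains), whereas
the mean of independent per-member AUCs converges to chance at the usual
root-n rate.

Evaluation reports sensitivity, specificity, positive/negative precision,
F1, Matthews correlation (all at threshold 0.5) and threshold-free AUC;
permutation importance shuffles one feature at a time on held-out nights
and records the F1 drop. Nightly scores map to severity categories 1–6 by
equal-width sextiles on `[0, 1]`, half-open with a closed top bin — the cut
points are a convention, as none are published.

The clinical association model is
`score ~ dri_mean + dri_var + age + sex + (1 | participant)`, fitted by
REML via `lme4`, one model per clinical scale (ADAS-Cog, NPI, BADL, PSQI),
with the 90-day window mean and variance (sample variance, n − 1) of the
nightly index as exposures, age in years uncentered and sex coded 0/1.
Wald Z statistics are reported; boundary (zero) random-intercept variance
and non-convergence are flagged, never silently replaced. The window
variance enters as a variance, not a standard deviation, matching the
squared term in the printed model.

## 5. The synthetic cohort generator

No raw cohort of this kind is publicly deposited, so the package generates
its own, with enough fidelity that every pipeline stage is testable against
planted ground truth.

A `night_profile` holds the generative parameters of one group: normal
bed-entry and arise clock times, a Poisson exit rate with log-normal exit
durations, a nap probability, per-minute heart/respiration parameters, a
per-minute snore probability and a 4-state sticky Markov chain
(`P = a·I + (1−a)·1πᵀ`, whose stationary distribution is exactly the
target state composition π). The canned profiles encode published
group-level descriptives: AD-like sleepers enter bed at 22:47 ± 2.8 h,
arise at 08:29 ± 2.4 h, exit 3.5 times a night for 9.6 min on average, nap
more, snore less, and show more awake and less deep/REM time; older adults
(60–100) arise at 07:52 ± 2.5 h with 3.1 exits of 8.7 min; young adults
retire at 23:59 ± 1.9 h with 2.3 short exits. Each participant draws a
latent disturbance scalar `z` that jointly shifts bedtime earlier, arise
later and the exit rate up (and enters clinical scale scores linearly), so
sleep–clinical associations exist by construction and are recoverable.

Choices worth knowing about:

- *Exit truncation.* Exit durations are log-normal truncated to 1–29
  minutes, and overlapping exits merge with their union capped at 29
  absent minutes. A longer absence would split the night under the
  30-minute episode rule, destroying the night-level bookkeeping that the
  exact-recovery tests rely on. The published real-data dispersion
  (9.6 ± 23.9 min) is heavier-tailed; the generator keeps the mean and
  sacrifices the tail.
- *Night-level random effects.* Nightly snore propensity is scaled by a
  log-normal factor and nightly HR/RR levels are shifted by normal draws.
  Without them, per-minute i.i.d. draws make nightly means nearly
  deterministic and any two groups separable at AUC ≈ 1, which real sensor
  data are not.
- *Within-night physiology is i.i.d.* around the nightly level; no
  autocorrelation structure is published for these streams, so none is
  asserted. Consequences for methods sensitive to within-night dynamics
  are out of scope — nothing downstream consumes them.
- *Determinism.* All randomness flows from one seed through `child_seed`,
  a multiplicative hash with extra scrambling rounds (consecutive
  `set.seed` values produce correlated Mersenne–Twister streams in early
  draws; the scrambling keeps derived sub-streams well separated). Each
  participant owns a sub-stream, so cohorts are reproducible and
  memory-bounded streaming generation (`simulate_night_metrics`) is
  bit-identical to materializing all minutes first.
- *Null cohorts* for calibration use identical profiles **and**
  `disturbance_sd = 0`: the hypothesis under test is "no group
  difference", and per-participant heterogeneity with a handful of
  held-out participants would swamp the AUC estimate with cluster noise
  unrelated to that hypothesis.

What passing tests on generated data do *not* show: that the generator's
group geometry matches real cohorts. One visible divergence: under the
canned profiles, the strongest AD-vs-older-adult separators are snore
proportion and state composition, whereas the published real-data finding
puts bed exits and exit duration first — real data evidently carry more
night-to-night exit variation relative to between-group timing differences
than the generator does. The permutation-importance machinery is therefore
validated on controlled constructions where a single feature carries the
planted signal, not on the canned profiles.

## 6. Problem sizes and test design

The test-suite and acceptance-script scales are the package's chosen
simulation designs: 600 nights from 3 planted timing/exit regimes (and 40
participants from 4 proportion archetypes) for clustering recovery; a
20-participant separable cohort for leave-one-group-out classification;
40 + 400 participants × 180 nights with a 50-member ensemble for the index
(the full protocol contemplates 1000 members; the ensemble size is a
parameter); 1000 simulations for Welch type-I calibration; 100 REML fits
each for coefficient coverage and null calibration (80 participants × 6
assessments, β₁ = 0.8, random-intercept SD 0.5, residual SD 1; ±2·SE
nominal coverage is ~95%, so the ≥93/100 check is expected to pass for
most but not every seed). Runtimes are minutes on one CPU.

## 7. Known limitations

- The sensor's sleep-state estimates correlate poorly with
  polysomnography in older adults; state-composition metrics are carried
  for completeness and interpretability, not as validated staging.
- The combined night dissimilarity is not metric in general (min-max
  normalization is dataset-scoped), and Ward linkage on a non-Euclidean
  dissimilarity is a faithful reproduction of the source procedure rather
  than a geometrically principled choice.
- Greedy propensity matching is order-dependent by design (stable id
  order); optimal matching is out of scope.
- The mixed model's Wald inference ignores finite-cluster df corrections;
  with ≥ 80 participants the effect is negligible, with far fewer it would
  not be.
- Nights are assumed to come from one sensor per sleeper; co-sleeping,
  device relocation and multi-resident homes are not modelled.
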