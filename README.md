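# drisleep

Nightly sleep metrics, bed-occupancy phenotypes and an ensemble
sleep-disturbance index from contactless under-mattress sensor data.

Under-mattress pressure sensors record one observation per occupied minute
— a timestamp, heart-rate and respiration-rate approximations, a snore flag
and a four-level sleep-state estimate — for months or years, with zero
burden on the sleeper. That makes them attractive for monitoring people
living with dementia, whose sleep is often disturbed (long times in bed,
frequent night-time bed exits, altered timing) and who cannot reliably
self-report. `drisleep` implements the full analysis chain from those raw
minute streams to interpretable, clinically oriented summaries, for
researchers working with this kind of longitudinal bed-sensor data.

## What the package computes

**Nightly metrics.** Observations are localized to the sleeper's time zone,
assigned to noon-to-noon windows, and resolved into bed periods (runs of
consecutive occupied minutes). Periods separated by gaps under 30 minutes
merge into episodes; episodes starting between 08:00 and 20:00 and ending
the same day are diurnal naps, the rest nocturnal. For the principal
nocturnal episode of each night the package computes, by integer-minute
arithmetic:

- timing: going-to-bed and arise clock times, also as angles at 15°/hour
  (`TO_BED` from a midday origin, `ARISE` from midnight);
- occupancy: the nocturnal occupancy period `NOP` (first-to-last
  observation, inclusive), in-bed time `IBT` (occupied minutes / 60),
  out-of-bed time `OBT = NOP − IBT` and the ratio `IBP = IBT/NOP`;
- fragmentation: `EXITS` (gaps of ≥ 2 minutes between consecutive
  observations) and the mean exit duration `EXIT_DUR = 60·OBT/EXITS`;
- composition and physiology: per-state durations and proportions
  (`WSA_AWAKE/LIGHT/DEEP/REM`), snore minutes `SNT` and proportion `SNR`,
  mean `HR` and `RR`.

Nights with extreme or invalid values are removed by a predefined filter
(≤ 20 exits, `IBP` 0.6–1.0, `HR` 45–85 bpm, `RR` 10–25 cpm, mean exit
duration ≤ 60 min, `OBT` < 180 min, `IBT` 4–16 h, bedtime 17:20–03:00,
wake-up 02:40–23:45), each night carrying the list of rules it violated.

**Group comparison.** Because cohorts can differ in size by orders of
magnitude, groups are compared distribution-to-distribution with the
Hellinger distance `H(P,Q) = √(½ Σ (√pᵢ − √qᵢ)²)` on canonically binned
metrics, rather than by p-values from overpowered tests. Timing
associations use the Fisher–Lee circular correlation with bootstrap
confidence intervals; case–control designs are balanced by logistic
propensity-score matching (up to 10 nearest controls per case).

**Phenotypes.** Nights are collapsed to 96 quarter-hour occupancy counts;
a combined dissimilarity (equal-weight, min-max-normalized mean of the
Jaccard distance between non-occupancy masks and the Euclidean distance
between counts) feeds Ward hierarchical clustering, with the number of
bed-occupancy phenotypes chosen by the Davies–Bouldin score and labels
ordered by mean occupancy duration. An interpretable additive boosted
classifier (depth-one stumps, the additive structure of explainable
boosting machines) learns the phenotypes from seven nightly metrics and is
validated leave-one-participant-out, so it can label nights from cohorts
never touched by the clustering. 90-day pre-assessment windows are
summarized as phenotype-proportion vectors and clustered with Hellinger
distances (Ward for assessment states, complete linkage with silhouette
selection for participant groups); group effects on behavioral and clinical
outcomes use Welch's ANOVA with Games–Howell post hoc tests, Levene checks
and Bonferroni correction.

**The sleep-disturbance index.** A nightly 0–1 score distinguishing
case-like from control-like nights: an ensemble of additive boosted binary
classifiers, each trained on a stratified participant bootstrap with
quasi-random temporal night sampling and 1:1 random under-sampling, merged
by averaging. Evaluation uses a multi-level split — a held-out participant
fraction (naive test) and each training participant's last 30 days
(horizon test) — against label-shuffled dummy baselines, with permutation
feature importance on held-out nights. Scores aggregate over 90-day
pre-assessment windows and relate to clinical scale scores through a
mixed-effects model with a participant random intercept
(`score ~ dri_mean + dri_var + age + sex + (1 | participant)`).

**Synthetic cohorts.** Real streams of this kind are not freely
redistributable, so the package ships a generator that emulates the record
structure and published group-level descriptives (bedtimes, arise times,
exit rates and durations, state composition, snoring) with a per-participant
latent disturbance linking sleep behavior to clinical scores. Every stage
of the pipeline is tested against cohorts whose ground truth is known by
construction.

## Worked example

Simulate a small cohort (12 AD-like, 48 older-adult control participants,
90 nights each), compute and filter nightly metrics, compare the groups,
and train a 20-member index:

```r
library(drisleep)
library(data.table)

spec <- cohort_spec(list(
  cohort_group("AD",  12, 90, profile_ad(),          age_mean = 82.2, age_sd = 7.7),
  cohort_group("POP", 48, 90, profile_older_adult(), age_mean = 81.3, age_sd = 7.5)),
  seed = 2024)
cohort <- simulate_night_metrics(spec)
cohort
#> <cohort_nights> 4747 kept nights from 60 participants (AD, POP)

head(cohort$nights[, .(participant_id, night_date, to_bed, wake_up,
                       IBT, EXITS, EXIT_DUR)], 3)
#>    participant_id night_date to_bed wake_up      IBT EXITS EXIT_DUR
#> 1:         AD_001 2021-01-01  02:05   07:25 5.300000     1 3.000000
#> 2:         AD_001 2021-01-02  02:50   08:27 4.816667     6 8.166667
#> 3:         AD_001 2021-01-03  01:28   06:59 5.200000     4 5.000000

compare_groups(cohort$nights, metrics = c("IBT", "EXITS", "HR"),
               groups = cohort$nights$group)
#>    metric group1 group2   distance small_sample
#> 1:    IBT     AD    POP 0.08546098        FALSE
#> 2:  EXITS     AD    POP 0.06056488        FALSE
#> 3:     HR     AD    POP 0.04812671        FALSE

nights <- copy(cohort$nights)[, label := as.integer(group == "AD")]
plan <- split_multilevel(nights, seed = 11)
ens <- train_dri_si(plan$nights[partition == "train"], n_members = 20, seed = 12)
evaluate_index(ens, plan$nights[partition == "naive"])
#> <eval_report> 471 nights
#>   ensemble:  sensitivity specificity precision_pos precision_neg    f1   mcc   auc
#>         0.85       0.847         0.531         0.965 0.654 0.588 0.929
#>   dummy baseline:  sensitivity specificity precision_pos precision_neg    f1    mcc   auc
#>        0.449       0.528         0.163         0.824 0.239 -0.017 0.477
```

The Hellinger distances say the two groups differ most in in-bed time and
bed exits and barely in heart rate, as planted by the generating profiles.
The index reaches AUC 0.93 on participants it has never seen, while the
label-shuffled dummy stays at chance (AUC 0.48) — the separation is signal,
not leakage.

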