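## Shared fixtures: hand-constructed minute streams and night records.

## Build a minute-observation table from "HH:MM-HH:MM" block strings.
## Blocks run within the noon-to-noon window starting on `date`; clock times
## before 12:00 belong to the following calendar day. The end minute is
## included (a block "22:00-06:59" covers 22:00 through 06:59).
make_obs <- function(blocks, date = "2021-06-01", participant = "p1",
                     state = "LIGHT", hr = 60, rr = 15, snore = 0L,
                     tz = "UTC") {
  noon <- as.POSIXct(paste(date, "12:00:00"), tz = tz)
  off <- unlist(lapply(blocks, function(b) {
    hm <- strsplit(strsplit(b, "-", fixed = TRUE)[[1]], ":")
    mins <- vapply(hm, function(x) {
      h <- as.integer(x[1]); m <- as.integer(x[2])
      as.integer(((h - 12) %% 24) * 60 + m)
    }, integer(1))
    mins[1]:mins[2]
  }))
  n <- length(off)
  data.table::data.table(
    participant_id = participant,
    timestamp = noon + off * 60,
    heart_rate = rep_len(hr, n),
    respiration_rate = rep_len(rr, n),
    snoring = rep_len(as.integer(snore), n),
    state = rep_len(state, n))
}

## A fully compliant night record (passes every quality filter).
compliant_record <- function(participant = "p1", night_date = "2021-06-01",
                             ...) {
  rec <- data.table::data.table(
    participant_id = participant, night_date = as.Date(night_date),
    to_bed = "22:00", wake_up = "07:00",
    TO_BED = 150, ARISE = 105, NOP = 9, IBT = 8.8, IBP = 8.8 / 9,
    OBT = 0.2, EXITS = 2, EXIT_DUR = 6,
    DEEP_DUR = 1.5, AWAKE_DUR = 1.0, REM_DUR = 1.0, LIGHT_DUR = 5.3,
    SNT = 30, WSA_DEEP = 1.5 / 8.8, WSA_AWAKE = 1.0 / 8.8,
    WSA_REM = 1.0 / 8.8, WSA_LIGHT = 5.3 / 8.8,
    HR = 62, RR = 15, SNR = 30 / (8.8 * 60))
  mods <- list(...)
  for (nm in names(mods)) data.table::set(rec, j = nm, value = mods[[nm]])
  rec
}

## Three well-separated bed-occupancy regimes used in planted-recovery tests:
## early fragmented long nights, consolidated normative nights, late short
## nights.
three_phenotype_spec <- function(n_participants = 10L, nights = 20L,
                                 seed = 5L) {
  mk <- function(tb, ar, ex, lab) {
    cohort_group(lab, n_participants, nights,
                 night_profile(to_bed_mean = tb, to_bed_sd = 0.5,
                               arise_mean = ar, arise_sd = 0.5,
                               exit_rate = ex, exit_dur_mean = 8,
                               nap_prob = 0))
  }
  cohort_spec(list(mk("19:30", "08:00", 8, "earlyfrag"),
                   mk("23:30", "06:30", 0.5, "normative"),
                   mk("02:00", "09:30", 2, "lateshort")),
              seed = seed)
}

## Four phenotype-proportion archetypes with Dirichlet noise around them.
archetype_proportions <- function(n_per = 10L, conc = 60, seed = 1L) {
  arch <- rbind(c(0.70, 0.10, 0.10, 0.05, 0.05),
                c(0.05, 0.70, 0.10, 0.10, 0.05),
                c(0.10, 0.05, 0.70, 0.05, 0.10),
                c(0.05, 0.10, 0.05, 0.70, 0.10))
  set.seed(seed)
  P <- do.call(rbind, lapply(seq_len(nrow(arch)), function(a) {
    t(vapply(seq_len(n_per), function(i) {
      g <- rgamma(ncol(arch), shape = arch[a, ] * conc)
      g / sum(g)
    }, numeric(ncol(arch))))
  }))
  colnames(P) <- paste0("prop_", seq_len(ncol(arch)))
  list(P = P, truth = rep(seq_len(nrow(arch)), each = n_per))
}

## adjusted Rand index (mclust) -- used as the planted-recovery criterion
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
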