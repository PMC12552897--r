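## Synthetic cohort generator
##
## Emulates the record structure of minute-level under-mattress sleep sensors:
## one row per occupied minute carrying heart rate, respiration rate, a snore
## flag and a four-level sleep-state estimate. Group-level timing parameters
## default to published descriptives for people with Alzheimer's disease and
## general-population age bands, so the generated cohorts carry the group
## differences the downstream analysis is designed to detect.

#' Build a row-stochastic sleep-state transition matrix
#'
#' Constructs `P = a*I + (1-a) * 1 %*% t(pi)`, a sticky Markov chain whose
#' stationary distribution is exactly `pi`. Used so that a profile's target
#' sleep-state composition is reproduced in expectation by the minute-level
#' chain.
#'
#' @param pi length-4 stationary distribution over
#'   `c("AWAKE", "LIGHT", "DEEP", "REM")`; must sum to 1.
#' @param stickiness probability mass added to staying in the current state.
#' @return a 4x4 row-stochastic matrix with dimnames.
#' @export
state_transition_matrix <- function(pi, stickiness = 0.88) {
  stopifnot(length(pi) == 4L, abs(sum(pi) - 1) < 1e-9, stickiness >= 0,
            stickiness < 1)
  P <- stickiness * diag(4) + (1 - stickiness) * matrix(pi, 4, 4, byrow = TRUE)
  dimnames(P) <- list(STATE_LEVELS, STATE_LEVELS)
  P
}

#' Nightly generating profile for one cohort group
#'
#' Bundles the distributional parameters from which individual nights are
#' sampled: going-to-bed and arise clock times (normal on the wall clock),
#' a Poisson bed-exit rate with log-normal exit durations, a daytime-nap
#' probability, per-minute heart/respiration parameters, a per-minute snore
#' probability and the sleep-state transition matrix.
#'
#' @param to_bed_mean,arise_mean clock times ("HH:MM") of mean bed entry/exit.
#' @param to_bed_sd,arise_sd standard deviations in hours.
#' @param exit_rate expected number of bed exits per night (Poisson mean).
#' @param exit_dur_mean mean exit duration in minutes (log-normal; durations
#'   are truncated to 1--29 minutes so an exit never splits the nocturnal
#'   episode under the < 30 minute period-clustering rule).
#' @param nap_prob probability of one diurnal bed period on a given day.
#' @param hr_mean,hr_sd per-minute heart rate parameters (beats/min).
#' @param rr_mean,rr_sd per-minute respiration rate parameters (cycles/min).
#' @param snore_prob per-minute probability of a snore flag.
#' @param state_transition 4x4 row-stochastic matrix over
#'   `AWAKE, LIGHT, DEEP, REM`; see [state_transition_matrix()].
#' @return an object of class `night_profile`.
#' @seealso [profile_ad()], [profile_older_adult()], [profile_young_adult()]
#' @export
night_profile <- function(to_bed_mean = "22:47", to_bed_sd = 2.8,
                          arise_mean = "08:29", arise_sd = 2.4,
                          exit_rate = 3.5, exit_dur_mean = 9.6,
                          nap_prob = 0.2,
                          hr_mean = 62, hr_sd = 6,
                          rr_mean = 15, rr_sd = 2,
                          snore_prob = 0.08,
                          state_transition =
                            state_transition_matrix(c(0.20, 0.55, 0.15, 0.10))) {
  p <- list(to_bed_mean = to_bed_mean, to_bed_sd = to_bed_sd,
            arise_mean = arise_mean, arise_sd = arise_sd,
            exit_rate = exit_rate, exit_dur_mean = exit_dur_mean,
            nap_prob = nap_prob, hr_mean = hr_mean, hr_sd = hr_sd,
            rr_mean = rr_mean, rr_sd = rr_sd, snore_prob = snore_prob,
            state_transition = state_transition)
  class(p) <- "night_profile"
  validate_night_profile(p)
  p
}

validate_night_profile <- function(p) {
  sds <- c(p$to_bed_sd, p$arise_sd, p$hr_sd, p$rr_sd)
  if (any(sds < 0)) stop("profile standard deviations must be >= 0")
  probs <- c(p$nap_prob, p$snore_prob)
  if (any(probs < 0 | probs > 1)) stop("profile probabilities must be in [0,1]")
  if (p$exit_rate < 0) stop("exit_rate must be >= 0")
  if (p$exit_dur_mean <= 0) stop("exit_dur_mean must be > 0")
  P <- p$state_transition
  if (!is.matrix(P) || any(dim(P) != 4L) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("state_transition must be a 4x4 row-stochastic matrix")
  }
  tb <- hours_since_noon(parse_clock(p$to_bed_mean))
  ar <- hours_since_noon(parse_clock(p$arise_mean))
  if (ar <= tb) {
    stop("degenerate profile: arise_mean must fall after to_bed_mean ",
         "within the noon-to-noon night window")
  }
  invisible(p)
}

#' @export
print.night_profile <- function(x, ...) {
  cat("<night_profile>\n")
  cat(sprintf("  to bed  %s +/- %.1f h   arise %s +/- %.1f h\n",
              x$to_bed_mean, x$to_bed_sd, x$arise_mean, x$arise_sd))
  cat(sprintf("  exits/night %.2f (mean dur %.1f min)   nap prob %.2f\n",
              x$exit_rate, x$exit_dur_mean, x$nap_prob))
  cat(sprintf("  HR %.0f +/- %.0f bpm   RR %.0f +/- %.0f cpm   snore %.2f\n",
              x$hr_mean, x$hr_sd, x$rr_mean, x$rr_sd, x$snore_prob))
  invisible(x)
}

#' Canned group profiles
#'
#' Profiles parameterized from published group descriptives: people with
#' Alzheimer's disease go to bed early (22:47 +/- 2.8 h), arise late
#' (08:29 +/- 2.4 h), exit bed often (3.5 exits/night, mean duration
#' 9.6 min), nap more and snore less, with more awake time and less deep/REM
#' sleep; older adults (60-100 y) arise early (07:52 +/- 2.5 h) with 3.1
#' exits of 8.7 min; young adults (18-40 y) retire late (23:59 +/- 1.9 h)
#' with few, short exits (2.3 exits, 4.3 min) and the most REM.
#'
#' @return a [night_profile()].
#' @export
profile_ad <- function() {
  night_profile(to_bed_mean = "22:47", to_bed_sd = 2.8,
                arise_mean = "08:29", arise_sd = 2.4,
                exit_rate = 3.5, exit_dur_mean = 9.6, nap_prob = 0.35,
                hr_mean = 62, hr_sd = 6, rr_mean = 15, rr_sd = 2,
                snore_prob = 0.04,
                state_transition =
                  state_transition_matrix(c(0.223, 0.532, 0.155, 0.090)))
}

#' @rdname profile_ad
#' @export
profile_older_adult <- function() {
  night_profile(to_bed_mean = "22:44", to_bed_sd = 2.2,
                arise_mean = "07:52", arise_sd = 2.5,
                exit_rate = 3.1, exit_dur_mean = 8.7, nap_prob = 0.15,
                hr_mean = 62, hr_sd = 6, rr_mean = 15, rr_sd = 2,
                snore_prob = 0.10,
                state_transition =
                  state_transition_matrix(c(0.136, 0.500, 0.234, 0.130)))
}

#' @rdname profile_ad
#' @export
profile_young_adult <- function() {
  night_profile(to_bed_mean = "23:59", to_bed_sd = 1.9,
                arise_mean = "08:50", arise_sd = 2.1,
                exit_rate = 2.3, exit_dur_mean = 4.3, nap_prob = 0.05,
                hr_mean = 62, hr_sd = 6, rr_mean = 15, rr_sd = 2,
                snore_prob = 0.04,
                state_transition =
                  state_transition_matrix(c(0.143, 0.500, 0.180, 0.177)))
}

#' Define one group of a synthetic cohort
#'
#' @param label group label (unique within a spec).
#' @param n_participants,nights_per_participant cohort dimensions.
#' @param profile a [night_profile()].
#' @param age_mean,age_sd,prop_male demographics sampled per participant.
#' @param disturbance_sd spread of the per-participant latent disturbance
#'   scalar that jointly modulates bed exits, in-bed time and clinical scale
#'   scores (0 disables participant heterogeneity).
#' @return a list consumed by [cohort_spec()].
#' @export
cohort_group <- function(label, n_participants, nights_per_participant,
                         profile, age_mean = 82, age_sd = 7,
                         prop_male = 0.5, disturbance_sd = 1) {
  stopifnot(n_participants >= 1, nights_per_participant >= 1)
  validate_night_profile(profile)
  list(label = label, n_participants = as.integer(n_participants),
       nights_per_participant = as.integer(nights_per_participant),
       profile = profile, age_mean = age_mean, age_sd = age_sd,
       prop_male = prop_male, disturbance_sd = disturbance_sd)
}

#' Specification of a synthetic cohort
#'
#' @param groups list of [cohort_group()] definitions.
#' @param seed integer; fixes all randomness (per-participant sub-streams are
#'   derived with [child_seed()]).
#' @param assessment_schedule named integer vector: days between successive
#'   administrations of each clinical scale.
#' @param effect_map named list, one entry per scale, each
#'   `c(intercept, slope, sd)`: scores are generated as
#'   `intercept + slope * z + N(0, sd)` where `z` is the participant's latent
#'   disturbance.
#' @param start_date first night date.
#' @param tz time zone of the generated timestamps.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, seed,
                        assessment_schedule = c("ADAS-Cog" = 180L, NPI = 90L,
                                                BADL = 90L, PSQI = 180L),
                        effect_map = list(
                          "ADAS-Cog" = c(30, 4, 6), "NPI" = c(20, 5, 8),
                          "BADL" = c(18, 4, 5), "PSQI" = c(8, 1.5, 3)),
                        start_date = as.Date("2021-01-01"), tz = "UTC") {
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate group labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  stopifnot(length(seed) == 1L, is.finite(seed))
  structure(list(groups = groups, seed = as.integer(seed),
                 assessment_schedule = assessment_schedule,
                 effect_map = effect_map, start_date = as.Date(start_date),
                 tz = tz),
            class = "cohort_spec")
}

## shift a profile by a participant's latent disturbance z: earlier bedtimes,
## later arise times and more exits for larger z (jointly longer IBT)
perturb_profile <- function(profile, z) {
  if (z == 0) return(profile)
  p <- profile
  p$to_bed_mean <- format_clock(parse_clock(profile$to_bed_mean) - 0.25 * z)
  p$arise_mean  <- format_clock(parse_clock(profile$arise_mean) + 0.25 * z)
  p$exit_rate   <- profile$exit_rate * exp(0.35 * z)
  ## keep the profile valid even for extreme z draws
  tb <- hours_since_noon(parse_clock(p$to_bed_mean))
  ar <- hours_since_noon(parse_clock(p$arise_mean))
  if (ar <= tb + 1) {
    p$to_bed_mean <- profile$to_bed_mean
    p$arise_mean <- profile$arise_mean
  }
  p
}

## Sample the latent plan of n nights under the current RNG state.
## Returns a list with per-night integer minute offsets (since local noon).
sample_night_plan <- function(profile, n) {
  tb_mu <- hours_since_noon(parse_clock(profile$to_bed_mean))
  ar_mu <- hours_since_noon(parse_clock(profile$arise_mean))
  tb <- pmin(pmax(rnorm(n, tb_mu, profile$to_bed_sd), 0.5), 22.5)
  ar <- rnorm(n, ar_mu, profile$arise_sd)
  ar <- pmin(pmax(ar, tb + 0.75), 23.95)
  first <- as.integer(round(tb * 60))
  last <- as.integer(round(ar * 60))
  span <- last - first + 1L

  k_draw <- rpois(n, profile$exit_rate)
  k <- pmin(k_draw, pmax(0L, (span - 2L) %/% 45L))
  K <- sum(k)
  sdlog <- 0.75
  meanlog <- log(profile$exit_dur_mean) - sdlog^2 / 2
  durs <- pmin(pmax(as.integer(round(rlnorm(K, meanlog, sdlog))), 1L), 29L)
  u_on <- runif(K)

  u_nap <- runif(n)
  nap_first <- as.integer(round(runif(n, 30, 360)))
  nap_len <- as.integer(round(runif(n, 20, 90)))

  night_idx <- rep.int(seq_len(n), k)
  offsets <- vector("list", n)
  exits_realized <- integer(n)
  exit_minutes <- integer(n)
  nap_on <- logical(n)
  nap_range <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    occ <- first[i]:last[i]
    if (k[i] > 0L) {
      sel <- which(night_idx == i)
      d <- durs[sel]
      lo <- first[i] + 1L
      hi <- pmax(lo, last[i] - d - 1L)
      on <- lo + as.integer(floor(u_on[sel] * (hi - lo + 1L)))
      absent <- unique(unlist(lapply(seq_along(on), function(j) {
        on[j]:min(on[j] + d[j] - 1L, last[i] - 1L)
      })))
      absent <- sort(absent[absent > first[i] & absent < last[i]])
      if (length(absent)) {
        ## overlapping or adjacent exits merge into one absence run; cap each
        ## run at 29 min so it can never split the nocturnal episode
        run <- cumsum(c(1L, diff(absent) > 1L))
        pos <- sequence(tabulate(run))
        absent <- absent[pos <= 29L]
      }
      occ <- setdiff(occ, absent)
    }
    dd <- diff(occ)
    exits_realized[i] <- sum(dd >= 2L)
    exit_minutes[i] <- span[i] - length(occ)
    if (u_nap[i] < profile$nap_prob) {
      n_last <- min(nap_first[i] + nap_len[i] - 1L, 479L, first[i] - 40L)
      if (n_last - nap_first[i] >= 9L) {   # require a nap of >= 10 minutes
        nap_on[i] <- TRUE
        nap_range[i, ] <- c(nap_first[i], n_last)
        occ <- c(nap_first[i]:n_last, occ)
      }
    }
    offsets[[i]] <- occ
  }
  list(first = first, last = last, span = span,
       occupied = vapply(offsets, length, integer(1)),
       exits = exits_realized, exit_minutes = exit_minutes,
       nap = nap_on, nap_range = nap_range, offsets = offsets)
}

## Simulate sleep-state sequences for nights with the given spans (minutes),
## vectorized across nights: one chain per night starting in LIGHT.
simulate_state_chains <- function(P, spans) {
  n <- length(spans)
  S <- max(spans)
  cum <- t(apply(P, 1L, cumsum))
  st <- matrix(NA_integer_, n, S)
  st[, 1L] <- 2L   # LIGHT
  if (S >= 2L) {
    for (t in 2:S) {
      u <- runif(n)
      prev <- st[, t - 1L]
      thr <- cum[prev, , drop = FALSE]
      st[, t] <- 1L + (u > thr[, 1L]) + (u > thr[, 2L]) + (u > thr[, 3L])
    }
  }
  st
}

## Realize a sampled plan as a minute-observation table.
realize_minutes <- function(plan, profile, dates, participant_id, tz) {
  n <- length(dates)
  st <- simulate_state_chains(profile$state_transition, plan$span)
  noon <- as.numeric(as.POSIXct(paste(dates, "12:00:00"), tz = tz))

  per_night <- vector("list", n)
  for (i in seq_len(n)) {
    off <- plan$offsets[[i]]
    night <- off >= plan$first[i]
    s <- integer(length(off))
    s[night] <- st[i, off[night] - plan$first[i] + 1L]
    per_night[[i]] <- list(off = off, s = s, nn = !night)
  }
  off_all <- unlist(lapply(per_night, `[[`, "off"))
  s_all <- unlist(lapply(per_night, `[[`, "s"))
  nap_all <- unlist(lapply(per_night, `[[`, "nn"))
  m <- length(off_all)
  ## nap minutes: iid draws from the chain's stationary distribution,
  ## obtained as the left eigenvector of the transition matrix
  if (any(nap_all)) {
    ev <- eigen(t(profile$state_transition))
    pi_st <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
    pi_st <- pi_st / sum(pi_st)
    s_all[nap_all] <- sample.int(4L, sum(nap_all), replace = TRUE,
                                 prob = pi_st)
  }
  ## night-level random effects: nightly physiology level and snore
  ## propensity vary between nights (a per-minute iid draw alone would make
  ## nightly means nearly deterministic, which real sensor data are not)
  hr_shift <- rnorm(n, 0, 2)
  rr_shift <- rnorm(n, 0, 1)
  snore_mult <- rlnorm(n, -0.5, 1)
  night_of <- rep.int(seq_len(n), vapply(per_night, function(x) length(x$off),
                                         integer(1)))
  hr <- rnorm(m, profile$hr_mean + hr_shift[night_of], profile$hr_sd)
  rr <- rnorm(m, profile$rr_mean + rr_shift[night_of], profile$rr_sd)
  sn <- rbinom(m, 1L, pmin(profile$snore_prob * snore_mult[night_of], 0.8))

  ts <- noon[night_of] + off_all * 60
  data.table(participant_id = participant_id,
             timestamp = as.POSIXct(ts, tz = tz, origin = "1970-01-01"),
             heart_rate = round(pmax(hr, 30), 1),
             respiration_rate = round(pmax(rr, 5), 1),
             snoring = sn,
             state = STATE_LEVELS[s_all])
}

#' Generate one night of minute observations
#'
#' Samples bed-entry and arise times, bed exits, an optional daytime nap, a
#' minute-level sleep-state Markov chain and per-minute physiology from a
#' [night_profile()], and returns the occupied minutes as observation rows.
#' Observations exist only for occupied minutes; bed exits appear as gaps of
#' at least one fully absent minute; all timestamps lie inside the
#' noon-to-noon window starting on `date`.
#'
#' @param profile a [night_profile()].
#' @param date calendar date on which the night's window starts (at noon).
#' @param seed optional integer; if supplied the night is reproducible.
#' @param participant_id label used in the output.
#' @param tz time zone of the timestamps.
#' @return a `data.table` with columns `participant_id`, `timestamp`,
#'   `heart_rate`, `respiration_rate`, `snoring`, `state`.
#' @export
generate_night <- function(profile, date, seed = NULL,
                           participant_id = "p1", tz = "UTC") {
  validate_night_profile(profile)
  date <- as.Date(date)
  if (!is.null(seed)) set.seed(seed)
  plan <- sample_night_plan(profile, 1L)
  realize_minutes(plan, profile, date, participant_id, tz)
}

## internal: flat participant metadata table for a spec
cohort_participants <- function(spec) {
  rows <- lapply(seq_along(spec$groups), function(g) {
    grp <- spec$groups[[g]]
    data.table(group = grp$label, g_idx = g, p_idx = seq_len(grp$n_participants),
               participant_id = sprintf("%s_%03d", grp$label,
                                        seq_len(grp$n_participants)),
               nights = grp$nights_per_participant)
  })
  meta <- rbindlist(rows)
  if (anyDuplicated(meta$participant_id)) {
    stop("duplicate participant labels across groups")
  }
  meta
}

## internal: everything generated for one participant (deterministic given
## spec$seed and the participant's position): demographics, latent z, minute
## table, truth rows and assessment rows.
simulate_participant <- function(spec, meta_row) {
  grp <- spec$groups[[meta_row$g_idx]]
  set.seed(child_seed(spec$seed, meta_row$g_idx, meta_row$p_idx))
  z <- rnorm(1, 0, grp$disturbance_sd)
  age <- rnorm(1, grp$age_mean, grp$age_sd)
  sex <- rbinom(1, 1L, grp$prop_male)   # 1 = male
  prof <- perturb_profile(grp$profile, z)
  dates <- spec$start_date + seq_len(meta_row$nights) - 1L
  plan <- sample_night_plan(prof, length(dates))
  minutes <- realize_minutes(plan, prof, dates, meta_row$participant_id,
                             spec$tz)
  truth_nights <- data.table(
    participant_id = meta_row$participant_id, night_date = dates,
    first_min = plan$first, last_min = plan$last, span = plan$span,
    occupied = plan$occupied - ifelse(plan$nap,
                                      plan$nap_range[, 2] -
                                        plan$nap_range[, 1] + 1L, 0L),
    exits = plan$exits, exit_minutes = plan$exit_minutes, nap = plan$nap)
  ## clinical assessments: interval-scheduled, score driven by latent z
  sched <- spec$assessment_schedule
  horizon <- max(dates)
  arows <- lapply(names(sched), function(sc) {
    first <- spec$start_date + sched[[sc]]
    if (first > horizon + 1L) return(NULL)
    ad <- seq(first, horizon + 1L, by = sched[[sc]])
    em <- spec$effect_map[[sc]]
    if (is.null(em)) em <- c(0, 0, 1)
    data.table(participant_id = meta_row$participant_id,
               assessment_date = as.Date(ad, origin = "1970-01-01"),
               scale = sc,
               score = em[1] + em[2] * z + rnorm(length(ad), 0, em[3]))
  })
  list(minutes = minutes,
       participant = data.table(participant_id = meta_row$participant_id,
                                group = meta_row$group, z = z,
                                age = age, sex = sex),
       truth_nights = truth_nights,
       assessments = rbindlist(arows))
}

#' Generate a full synthetic cohort
#'
#' Produces the three tables the analysis pipeline consumes: the minute-level
#' observation stream, the clinical assessment table, and a latent truth table
#' retaining each night's planted parameters (for parameter-recovery tests).
#' Each participant draws a latent disturbance scalar `z` that jointly shifts
#' bed-exit rate, bedtime/arise times (hence in-bed time) and clinical scale
#' scores, so associations between sleep disturbance and scale scores are
#' recoverable by construction.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `sleep_cohort` with elements `minutes`,
#'   `assessments`, `participants` (group, latent `z`, age, sex) and
#'   `truth_nights` (planted per-night interval, exits and durations).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  meta <- cohort_participants(spec)
  parts <- lapply(seq_len(nrow(meta)), function(i) {
    simulate_participant(spec, meta[i])
  })
  out <- list(minutes = rbindlist(lapply(parts, `[[`, "minutes")),
              assessments = rbindlist(lapply(parts, `[[`, "assessments")),
              participants = rbindlist(lapply(parts, `[[`, "participant")),
              truth_nights = rbindlist(lapply(parts, `[[`, "truth_nights")))
  class(out) <- c("sleep_cohort", class(out))
  out
}

#' @export
print.sleep_cohort <- function(x, ...) {
  cat("<sleep_cohort>\n")
  cat(sprintf("  %d participants, %d nights, %d minute observations\n",
              nrow(x$participants), nrow(x$truth_nights), nrow(x$minutes)))
  cat(sprintf("  %d clinical assessments (%s)\n", nrow(x$assessments),
              paste(unique(x$assessments$scale), collapse = ", ")))
  invisible(x)
}
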