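## Nightly sleep metrics: episode clustering, diurnal/nocturnal labelling,
## the per-night metric set (timing angles, in-bed/out-of-bed time, exits,
## sleep-state composition, physiology) and extreme-value quality filters.

#' Cluster bed periods separated by short gaps
#'
#' Greedily merges time-adjacent bed periods within the same noon-to-noon
#' window when the out-of-bed gap between them is shorter than 30 minutes;
#' clusters are maximal. Gaps of exactly 30 minutes (or more) split clusters.
#'
#' @param periods bed periods from [detect_transitions()].
#' @return the input with an added `cluster_id` (sequential within each
#'   participant-window).
#' @export
cluster_periods <- function(periods) {
  p <- as.data.table(periods)
  setorder(p, participant_id, night_date, start)
  p[, gap := as.numeric(start - shift(end), units = "mins"),
    by = .(participant_id, night_date)]
  p[, cluster_id := cumsum(is.na(gap) | gap >= 30),
    by = .(participant_id, night_date)]
  p[, gap := NULL]
  p[]
}

#' Classify bed clusters as diurnal or nocturnal
#'
#' A cluster is diurnal iff it starts between 08:00 and 20:00 local time
#' (half-open, so a 20:00 start is nocturnal) and ends on the same calendar
#' day; clusters starting outside that range or spanning midnight are
#' nocturnal.
#'
#' @param clustered output of [cluster_periods()].
#' @return one row per cluster: `participant_id`, `night_date`, `cluster_id`,
#'   `start`, `end`, `minutes` (occupied), `classification`.
#' @export
classify_clusters <- function(clustered) {
  cl <- clustered[, .(start = min(start), end = max(end),
                      minutes = sum(minutes)),
                  by = .(participant_id, night_date, cluster_id)]
  tz <- attr(cl$start, "tzone")
  if (is.null(tz)) tz <- "UTC"
  sh <- parse_clock(cl$start, tz = tz)
  ## end is half-open; the last occupied minute starts one minute earlier
  d0 <- as.Date(as.POSIXlt(cl$start, tz = tz))
  d1 <- as.Date(as.POSIXlt(cl$end - 60, tz = tz))
  cl[, classification := ifelse(sh >= 8 & sh < 20 & d0 == d1,
                                "diurnal", "nocturnal")]
  cl[]
}

#' Clock time as an angle
#'
#' Maps a clock time to degrees at 15 degrees per hour. With the `midday`
#' origin (used for going-to-bed times) the day runs from noon to next noon,
#' so hours before 12:00 are treated as `h + 24`; with the `midnight` origin
#' (used for arise times) the angle is simply 15 * hours.
#'
#' @param t clock time: "HH:MM", fractional hours, or POSIXct.
#' @param origin `"midday"` or `"midnight"`.
#' @param tz zone used if `t` is POSIXct.
#' @return angle in degrees, in `[0, 360)`.
#' @export
#' @examples
#' clock_angle("22:47", "midday")   # 161.75
#' clock_angle("23:45", "midnight") # 356.25
clock_angle <- function(t, origin = c("midday", "midnight"), tz = "UTC") {
  origin <- match.arg(origin)
  h <- parse_clock(t, tz = tz)
  if (origin == "midday") {
    h <- ifelse(h < 12, h + 24, h)
    (15 * (h - 12)) %% 360
  } else {
    (15 * h) %% 360
  }
}

#' Compute nightly sleep metrics from minute observations
#'
#' Runs the full nightly feature chain: assign observations to noon-to-noon
#' local windows, detect bed periods (runs of consecutive occupied minutes),
#' merge periods separated by gaps under 30 minutes into clusters, classify
#' clusters as diurnal or nocturnal, and compute the metric set for the
#' principal (most-observed) nocturnal cluster of each window.
#'
#' Metric definitions: `NOP` is the inclusive first-to-last observation span
#' in hours; `IBT` = observed minutes / 60; `OBT = NOP - IBT`;
#' `IBP = IBT/NOP`; `EXITS` counts gaps of >= 2 minutes between consecutive
#' observations; `EXIT_DUR = OBT * 60 / EXITS` (0 when there are no exits);
#' state durations are per-state observed minutes in hours, with
#' `WSA_* = *_DUR / IBT`; `SNT` is snore-flagged minutes and
#' `SNR = SNT / (IBT * 60)`; `HR`/`RR` average the non-missing per-minute
#' values. `TO_BED` and `ARISE` are [clock_angle()]s of the first and last
#' observation. The night date is the date of the last observation minus
#' 12 hours (i.e. the window's starting day).
#'
#' @param obs localized minute observations.
#' @return a `data.table` with one row per participant-night:
#'   `participant_id`, `night_date`, `to_bed`, `wake_up` and the 20 metric
#'   columns.
#' @export
night_metrics <- function(obs) {
  if (!nrow(obs)) return(empty_night_records())
  tz <- attr(obs$timestamp, "tzone")
  if (is.null(tz)) tz <- "UTC"
  dt <- data.table(participant_id = obs$participant_id,
                   t_min = floor(as.numeric(obs$timestamp) / 60),
                   heart_rate = obs$heart_rate,
                   respiration_rate = obs$respiration_rate,
                   snoring = obs$snoring,
                   state = obs$state)
  lf <- local_fields(obs$timestamp, tz)
  dt[, night_date := lf$night_date]
  dt[, clock := lf$clock]
  setorder(dt, participant_id, night_date, t_min)

  dt[, gap := t_min - shift(t_min), by = .(participant_id, night_date)]
  dt[, cluster_id := cumsum(is.na(gap) | gap >= 31),
     by = .(participant_id, night_date)]

  agg <- dt[, {
    span <- t_min[.N] - t_min[1] + 1
    k <- .N
    g <- gap[-1]
    ## night_date is a grouping value (length 1) inside this j
    list(first_clock = clock[1], last_clock = clock[.N],
         first_day = night_date[1] + (clock[1] < 12),
         last_day = night_date[1] + (clock[.N] < 12),
         span = span, k = k,
         exits = sum(g >= 2),
         deep = sum(state == "DEEP", na.rm = TRUE),
         awake = sum(state == "AWAKE", na.rm = TRUE),
         rem = sum(state == "REM", na.rm = TRUE),
         light = sum(state == "LIGHT", na.rm = TRUE),
         snt = sum(snoring == 1L, na.rm = TRUE),
         hr = mean(heart_rate, na.rm = TRUE),
         rr = mean(respiration_rate, na.rm = TRUE))
  }, by = .(participant_id, night_date, cluster_id)]

  agg[, classification := ifelse(first_clock >= 8 & first_clock < 20 &
                                   first_day == last_day,
                                 "diurnal", "nocturnal")]
  noct <- agg[classification == "nocturnal"]
  if (!nrow(noct)) return(empty_night_records())
  ## principal nocturnal cluster per window; nights longer than a circadian
  ## cycle are excluded upstream by the window bound (span <= window length)
  setorder(noct, participant_id, night_date, -k, cluster_id)
  noct <- noct[, .SD[1], by = .(participant_id, night_date)]

  noct[, `:=`(
    NOP = span / 60,
    IBT = k / 60,
    to_bed = format_clock(first_clock),
    wake_up = format_clock(last_clock),
    TO_BED = clock_angle(first_clock, "midday"),
    ARISE = clock_angle(last_clock, "midnight")
  )]
  noct[, `:=`(OBT = NOP - IBT, IBP = IBT / NOP, EXITS = as.numeric(exits))]
  noct[, EXIT_DUR := ifelse(EXITS == 0, 0, OBT * 60 / EXITS)]
  noct[, `:=`(DEEP_DUR = deep / 60, AWAKE_DUR = awake / 60,
              REM_DUR = rem / 60, LIGHT_DUR = light / 60,
              SNT = as.numeric(snt),
              WSA_DEEP = deep / k, WSA_AWAKE = awake / k,
              WSA_REM = rem / k, WSA_LIGHT = light / k,
              HR = ifelse(is.nan(hr), NA_real_, hr),
              RR = ifelse(is.nan(rr), NA_real_, rr))]
  noct[, SNR := SNT / k]
  out <- noct[, c("participant_id", "night_date", "to_bed", "wake_up",
                  NIGHT_METRIC_COLS), with = FALSE]
  setorder(out, participant_id, night_date)
  out[]
}

empty_night_records <- function() {
  out <- data.table(participant_id = character(),
                    night_date = as.Date(character()),
                    to_bed = character(), wake_up = character())
  for (cc in NIGHT_METRIC_COLS) out[, (cc) := numeric()]
  out[]
}

#' Compute the metric set for a single nocturnal cluster
#'
#' Convenience wrapper around [night_metrics()] for one cluster's member
#' observations; errors if the observations are empty or do not form a
#' nocturnal episode.
#'
#' @param cluster_obs minute observations of one bed cluster.
#' @return a one-row night record.
#' @export
compute_night_metrics <- function(cluster_obs) {
  if (!nrow(cluster_obs)) stop("cluster has no observations")
  rec <- night_metrics(cluster_obs)
  if (nrow(rec) != 1L) {
    stop("observations do not form a single nocturnal cluster")
  }
  rec
}

## quality-filter rule set: each returns TRUE when VIOLATED
filter_rules <- list(
  exits_max = function(r) !is.na(r$EXITS) & r$EXITS > 20,
  ibp_range = function(r) !is.na(r$IBP) & (r$IBP < 0.6 | r$IBP > 1.0),
  hr_range = function(r) !is.na(r$HR) & (r$HR < 45 | r$HR > 85),
  rr_range = function(r) !is.na(r$RR) & (r$RR < 10 | r$RR > 25),
  exit_dur_max = function(r) !is.na(r$EXIT_DUR) & r$EXIT_DUR > 60,
  obt_max = function(r) !is.na(r$OBT) & r$OBT >= 3,
  ibt_range = function(r) !is.na(r$IBT) & (r$IBT < 4 | r$IBT > 16),
  to_bed_window = function(r) {
    h <- parse_clock(r$to_bed)
    !clock_in_window(h, 17 + 20 / 60, 3)
  },
  wake_up_window = function(r) {
    h <- parse_clock(r$wake_up)
    !clock_in_window(h, 2 + 40 / 60, 23.75)
  },
  missing_values = function(r) {
    m <- as.matrix(r[, NIGHT_METRIC_COLS, with = FALSE])
    rowSums(is.na(m)) > 0
  }
)

#' Apply extreme-value quality filters to night records
#'
#' Nights are kept only when every predefined rule holds: at most 20 bed
#' exits; in-bed proportion 0.6--1.0; mean heart rate 45--85 beats/min; mean
#' respiration rate 10--25 cycles/min; average exit duration at most 60
#' minutes; out-of-bed time under 180 minutes (strict); in-bed time 4--16
#' hours; bedtime between 17:20 and 03:00 (wrapped across midnight); wake-up
#' between 02:40 and 23:45; and no missing metric values. All printed ranges
#' are inclusive except the out-of-bed bound. The verdict is a pure
#' per-night predicate: idempotent and order-invariant.
#'
#' @param records night records from [night_metrics()].
#' @return a `data.table`: `participant_id`, `night_date`, `kept`, and
#'   list-column `violated_rules` (empty character vector iff kept).
#' @export
apply_quality_filters <- function(records) {
  r <- as.data.table(records)
  viol <- vapply(names(filter_rules),
                 function(nm) filter_rules[[nm]](r),
                 logical(nrow(r)))
  if (nrow(r) == 1L) viol <- matrix(viol, nrow = 1L,
                                    dimnames = list(NULL, names(filter_rules)))
  rules <- colnames(viol)
  out <- data.table(participant_id = r$participant_id,
                    night_date = r$night_date,
                    kept = rowSums(viol) == 0,
                    violated_rules = lapply(seq_len(nrow(r)), function(i) {
                      rules[viol[i, ]]
                    }))
  out[]
}

#' Keep only nights passing the quality filters
#'
#' @param records night records from [night_metrics()].
#' @return the subset of `records` with a clean [apply_quality_filters()]
#'   verdict; the verdict table is attached as attribute `verdict`.
#' @export
filter_nights <- function(records) {
  v <- apply_quality_filters(records)
  out <- as.data.table(records)[v$kept]
  setattr(out, "verdict", v)
  out[]
}

utils::globalVariables(c("clock", "first_clock", "last_clock", "first_day",
                         "last_day", "span", "exits", "deep", "awake", "rem",
                         "light", "snt", "hr", "rr", "DEEP_DUR", "AWAKE_DUR",
                         "REM_DUR", "LIGHT_DUR", "WSA_DEEP", "WSA_AWAKE",
                         "WSA_REM", "WSA_LIGHT", "violated_rules"))
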