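## Ingest: typing, time-zone localization, occupancy gridding and
## bed-period detection for sparse minute-level observations.

## local wall-clock fields of a POSIXct vector: the noon-to-noon window date,
## the clock hour (fractional) and the calendar date
local_fields <- function(ts, tz) {
  lt <- as.POSIXlt(ts, tz = tz)
  clock <- lt$hour + lt$min / 60 + lt$sec / 3600
  cal <- as.Date(lt)
  list(night_date = cal - (clock < 12),
       clock = clock,
       cal_date = cal)
}

#' Localize, type and validate raw minute observations
#'
#' Parses timestamps (UTC/offset-qualified strings are converted to the
#' participant's zone; naive strings are interpreted as already-local),
#' enforces the observation schema, rejects rows with unparseable or
#' out-of-range required fields (with per-row diagnostics), floors timestamps
#' to the minute, drops duplicate (participant, timestamp) rows keeping the
#' first, and returns the stream stably ordered by participant and time.
#'
#' @param raw a data.frame with columns `participant_id`, `timestamp`
#'   (character ISO-8601 or POSIXct), `heart_rate`, `respiration_rate`,
#'   `snoring` (0/1 or logical), `state` (`AWAKE|LIGHT|DEEP|REM` or NA).
#' @param tz Olson zone name of the participant's locale.
#' @return a `data.table` of typed observations; attribute `rejected` holds a
#'   table of dropped rows with the offending field, attribute `n_duplicates`
#'   the number of duplicate rows removed.
#' @export
localize_observations <- function(raw, tz = "UTC") {
  if (!tz %in% OlsonNames()) stop("unknown time zone: ", tz)
  req <- c("participant_id", "timestamp", "heart_rate", "respiration_rate",
           "snoring", "state")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  dt <- as.data.table(raw)[, req, with = FALSE]

  if (inherits(dt$timestamp, "POSIXt")) {
    ts <- as.POSIXct(dt$timestamp)
    attr(ts, "tzone") <- tz
  } else {
    ts <- parse_iso_timestamps(as.character(dt$timestamp), tz)
  }
  hr <- suppressWarnings(as.numeric(dt$heart_rate))
  rr <- suppressWarnings(as.numeric(dt$respiration_rate))
  sn <- suppressWarnings(as.integer(dt$snoring))
  st <- toupper(as.character(dt$state))
  st[st %in% c("", "NA")] <- NA_character_

  bad_field <- rep(NA_character_, nrow(dt))
  flag <- function(cond, field) {
    bad_field[is.na(bad_field) & cond] <<- field
  }
  flag(is.na(ts), "timestamp")
  flag(!is.na(hr) & (hr <= 0 | hr >= 300), "heart_rate")
  flag(!is.na(rr) & (rr <= 0 | rr >= 100), "respiration_rate")
  flag(!is.na(sn) & !sn %in% c(0L, 1L), "snoring")
  flag(!is.na(st) & !st %in% STATE_LEVELS, "state")

  rejected <- which(!is.na(bad_field))
  diag <- data.table(row = rejected, field = bad_field[rejected],
                     value = vapply(rejected, function(i) {
                       as.character(dt[[bad_field[i]]][i])
                     }, character(1)))
  keep <- setdiff(seq_len(nrow(dt)), rejected)
  out <- data.table(participant_id = as.character(dt$participant_id[keep]),
                    timestamp = floor_minute(ts[keep]),
                    heart_rate = hr[keep], respiration_rate = rr[keep],
                    snoring = sn[keep], state = st[keep])
  setorder(out, participant_id, timestamp)
  dup <- duplicated(out, by = c("participant_id", "timestamp"))
  n_dup <- sum(dup)
  if (n_dup) out <- out[!dup]
  if (nrow(diag)) {
    message(nrow(diag), " row(s) rejected during ingest")
  }
  if (n_dup) message(n_dup, " duplicate (participant, timestamp) row(s) dropped")
  setattr(out, "rejected", diag)
  setattr(out, "n_duplicates", n_dup)
  out
}

## Parse ISO-8601 timestamps: offset-qualified strings are absolute instants
## re-expressed in tz; naive strings are taken as already-local wall clock.
parse_iso_timestamps <- function(x, tz) {
  x2 <- sub("Z$", "+0000", x)
  x2 <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x2)
  has_offset <- grepl("[+-]\\d{4}$", x2)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = tz,
                    origin = "1970-01-01")
  if (any(has_offset)) {
    parsed <- as.POSIXct(x2[has_offset],
                         format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
    alt <- is.na(parsed)
    if (any(alt)) {
      parsed[alt] <- as.POSIXct(x2[has_offset][alt],
                                format = "%Y-%m-%d %H:%M:%S%z", tz = tz)
    }
    out[has_offset] <- parsed
  }
  if (any(!has_offset)) {
    naive <- x2[!has_offset]
    parsed <- as.POSIXct(naive, format = "%Y-%m-%dT%H:%M:%S", tz = tz)
    for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
      alt <- is.na(parsed)
      if (!any(alt)) break
      parsed[alt] <- as.POSIXct(naive[alt], format = fmt, tz = tz)
    }
    out[!has_offset] <- parsed
  }
  out
}

floor_minute <- function(ts) {
  tz <- attr(ts, "tzone")
  out <- as.POSIXct(floor(as.numeric(ts) / 60) * 60, origin = "1970-01-01",
                    tz = if (is.null(tz)) "UTC" else tz)
  out
}

#' Resample observations onto per-night occupancy grids
#'
#' Assigns each localized observation to its noon-to-noon local window and
#' marks the corresponding minute cell occupied. One grid is returned per
#' window containing at least one observation. Grid length is the elapsed
#' minutes between consecutive local noons: 1440 on ordinary days, 1380/1500
#' on daylight-saving transition days.
#'
#' @param obs localized observations (see [localize_observations()]).
#' @return a `data.table` with one row per (participant, window):
#'   `participant_id`, `night_date`, `window_start` (local noon), `len`, and
#'   list-column `occupied` (integer 0/1 vector of length `len`).
#' @export
resample_occupancy <- function(obs) {
  if (!nrow(obs)) {
    return(data.table(participant_id = character(), night_date = as.Date(character()),
                      window_start = as.POSIXct(character()), len = integer(),
                      occupied = list()))
  }
  tz <- attr(obs$timestamp, "tzone")
  if (is.null(tz)) tz <- "UTC"
  lf <- local_fields(obs$timestamp, tz)
  dt <- data.table(participant_id = obs$participant_id,
                   night_date = lf$night_date,
                   t_num = as.numeric(obs$timestamp))
  grids <- dt[, {
    ws <- as.POSIXct(paste(night_date[1], "12:00:00"), tz = tz)
    we <- as.POSIXct(paste(night_date[1] + 1L, "12:00:00"), tz = tz)
    len <- as.integer(round((as.numeric(we) - as.numeric(ws)) / 60))
    cell <- as.integer(floor((t_num - as.numeric(ws)) / 60)) + 1L
    occ <- integer(len)
    occ[unique(cell[cell >= 1L & cell <= len])] <- 1L
    list(window_start = ws, len = len, occupied = list(occ))
  }, by = .(participant_id, night_date)]
  setorder(grids, participant_id, night_date)
  grids[]
}

#' Detect bed periods from occupancy grids
#'
#' Identifies transitions between in-bed and out-of-bed states as maximal
#' runs of occupied minutes; concatenating the returned periods reproduces
#' each grid exactly. Periods use the half-open convention `[start, end)`.
#'
#' @param grids output of [resample_occupancy()] (or a single grid row).
#' @return a `data.table`: `participant_id`, `night_date`, `start`, `end`
#'   (POSIXct), `minutes`.
#' @export
detect_transitions <- function(grids) {
  out <- lapply(seq_len(nrow(grids)), function(i) {
    occ <- grids$occupied[[i]]
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    onr <- r$values == 1L
    if (!any(onr)) return(NULL)
    ws <- as.numeric(grids$window_start[i])
    data.table(participant_id = grids$participant_id[i],
               night_date = grids$night_date[i],
               start_off = starts[onr] - 1L,
               end_off = ends[onr],
               minutes = r$lengths[onr],
               ws = ws)
  })
  out <- rbindlist(out)
  if (!nrow(out)) {
    return(data.table(participant_id = character(),
                      night_date = as.Date(character()),
                      start = as.POSIXct(character()),
                      end = as.POSIXct(character()), minutes = integer()))
  }
  tz <- attr(grids$window_start, "tzone")
  if (is.null(tz)) tz <- "UTC"
  res <- out[, .(participant_id, night_date,
                 start = as.POSIXct(ws + start_off * 60, origin = "1970-01-01",
                                    tz = tz),
                 end = as.POSIXct(ws + end_off * 60, origin = "1970-01-01",
                                  tz = tz),
                 minutes = minutes)]
  setorder(res, participant_id, night_date, start)
  res[]
}

utils::globalVariables(c("t_num", "ws", "start_off", "end_off"))
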