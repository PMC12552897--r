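## End-to-end pipeline glue: stream a synthetic cohort participant by
## participant through the nightly-metric and quality-filter stages without
## materializing the full minute-level table.

#' Simulate a cohort and compute its nightly metrics
#'
#' Generates each participant's minute stream, runs the nightly metric chain
#' and (optionally) the quality filters, and discards the minutes before
#' moving on -- memory use is bounded by one participant regardless of
#' cohort size. Output is identical to
#' `filter_nights(night_metrics(generate_cohort(spec)$minutes))` because the
#' per-participant random streams are the same.
#'
#' @param spec a [cohort_spec()].
#' @param filter apply [filter_nights()] to each participant's records.
#' @return list of class `cohort_nights`: `nights` (records joined with the
#'   participant's group, latent `z`, age and sex), `participants`,
#'   `assessments`, `truth_nights`.
#' @export
simulate_night_metrics <- function(spec, filter = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  meta <- cohort_participants(spec)
  nights <- vector("list", nrow(meta))
  parts <- vector("list", nrow(meta))
  assess <- vector("list", nrow(meta))
  truth <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sim <- simulate_participant(spec, meta[i])
    rec <- night_metrics(sim$minutes)
    if (filter) rec <- filter_nights(rec)
    nights[[i]] <- rec
    parts[[i]] <- sim$participant
    assess[[i]] <- sim$assessments
    truth[[i]] <- sim$truth_nights
  }
  nights <- rbindlist(nights)
  participants <- rbindlist(parts)
  nights <- merge(nights, participants, by = "participant_id", sort = FALSE)
  structure(list(nights = nights, participants = participants,
                 assessments = rbindlist(assess),
                 truth_nights = rbindlist(truth)),
            class = "cohort_nights")
}

#' @export
print.cohort_nights <- function(x, ...) {
  cat(sprintf("<cohort_nights> %d kept nights from %d participants (%s)\n",
              nrow(x$nights), nrow(x$participants),
              paste(unique(x$participants$group), collapse = ", ")))
  invisible(x)
}
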