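## Small shared helpers: deterministic seed streams, low-discrepancy indices,
## clock arithmetic. All clock times are wall-clock; fractional hours internally.

#' Derive a child seed from a master seed and an index path
#'
#' All randomness in the package flows from one user-supplied seed. Independent
#' sub-streams (per participant, per ensemble member, per shuffle) use child
#' seeds derived with a multiplicative-congruential hash, so adding or removing
#' one consumer never shifts the draws of another. Results stay below 2^31 - 1
#' and are valid arguments to [set.seed()].
#'
#' @param seed integer master seed.
#' @param ... integer indices identifying the sub-stream (e.g. participant
#'   number, iteration number).
#' @return a single integer seed.
#' @export
#' @examples
#' child_seed(1, 3)
#' child_seed(1, 3, 7)
child_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629
  h <- as.numeric(seed) %% m
  for (k in idx) {
    h <- (h * 69069 + as.numeric(k) + 1) %% m
    ## extra scrambling rounds: a single congruential step maps consecutive
    ## indices to consecutive seeds, whose Mersenne-Twister streams are
    ## noticeably correlated in their first draws
    h <- (h * 48271 + 11) %% m
    h <- (h * 69621 + 1013904223) %% m
  }
  as.integer(h)
}

#' Van der Corput low-discrepancy sequence
#'
#' Base-2 bit-reversal radical inverse, used by the quasi-random temporal
#' night sampler to pick well-spread indices inside timeline blocks.
#'
#' @param k non-negative integer index (vectorized).
#' @param base integer base, default 2.
#' @return values in `[0, 1)`.
#' @export
van_der_corput <- function(k, base = 2L) {
  vapply(k, function(ki) {
    x <- 0
    f <- 1 / base
    while (ki > 0) {
      x <- x + f * (ki %% base)
      ki <- ki %/% base
      f <- f / base
    }
    x
  }, numeric(1))
}

#' Parse a clock time to fractional hours
#'
#' @param x "HH:MM" character, numeric hours, or POSIXct.
#' @param tz time zone used when `x` is POSIXct.
#' @return numeric hours in `[0, 24)`.
#' @export
parse_clock <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x, tz = tz)
    return(lt$hour + lt$min / 60 + lt$sec / 3600)
  }
  if (is.numeric(x)) return(x %% 24)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 2L || anyNA(suppressWarnings(as.numeric(p[1:2])))) {
      stop("cannot parse clock time: ", paste(p, collapse = ":"), call. = FALSE)
    }
    (as.numeric(p[1]) + as.numeric(p[2]) / 60) %% 24
  }, numeric(1))
}

## hours after the preceding midday (0 = noon, 23.99 = just before next noon)
hours_since_noon <- function(h) (h - 12) %% 24

## format fractional hours as "HH:MM"
format_clock <- function(h) {
  h <- h %% 24
  hh <- floor(h)
  mm <- round((h - hh) * 60)
  hh <- (hh + mm %/% 60) %% 24
  mm <- mm %% 60
  sprintf("%02d:%02d", hh, mm)
}

## is clock hour h inside the (possibly midnight-wrapped) window [lo, hi]?
clock_in_window <- function(h, lo, hi) {
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}
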