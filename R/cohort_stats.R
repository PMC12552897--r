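## Distribution-level group comparison (Hellinger distance), circular timing
## correlation with bootstrap confidence intervals, and propensity-score
## matching of cases to population controls.

#' Discretize metric values into a binned probability distribution
#'
#' @param values numeric vector (at least one finite value).
#' @param bin_edges strictly increasing edge vector; values outside the outer
#'   edges are clipped into the end bins.
#' @param metric optional metric name carried along for bookkeeping.
#' @return an object of class `metric_distribution`: list with `metric`,
#'   `bin_edges` and `probabilities` (summing to 1).
#' @export
bin_metric <- function(values, bin_edges, metric = NA_character_) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to bin")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  nb <- length(bin_edges) - 1L
  clipped <- pmin(pmax(values, bin_edges[1]), bin_edges[length(bin_edges)])
  idx <- findInterval(clipped, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = nb)
  structure(list(metric = metric, bin_edges = bin_edges,
                 probabilities = counts / sum(counts)),
            class = "metric_distribution")
}

#' Hellinger distance between two binned distributions
#'
#' `H(P, Q) = sqrt(0.5 * sum((sqrt(p_i) - sqrt(q_i))^2))`: a bounded
#' f-divergence in `[0, 1]` that is robust to severe sample-size imbalance,
#' used in place of classical two-sample tests when one group has orders of
#' magnitude more nights than the other.
#'
#' @param P,Q [bin_metric()] objects sharing identical bin edges, or bare
#'   probability vectors of equal length.
#' @return the distance, a scalar in `[0, 1]`.
#' @export
#' @examples
#' hellinger(c(0.5, 0.5), c(1, 0))  # 0.541196...
hellinger <- function(P, Q) {
  p <- if (inherits(P, "metric_distribution")) P$probabilities else P
  q <- if (inherits(Q, "metric_distribution")) Q$probabilities else Q
  if (inherits(P, "metric_distribution") &&
      inherits(Q, "metric_distribution") &&
      !isTRUE(all.equal(P$bin_edges, Q$bin_edges))) {
    stop("distributions must share identical bin edges")
  }
  if (length(p) != length(q)) stop("probability vectors differ in length")
  sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
}

## Canonical bin edges per metric: 50 equal-width bins spanning the
## filter-admissible range (integer bins for exit counts).
default_bin_edges <- function(metric) {
  ranges <- list(IBT = c(4, 16), IBP = c(0.6, 1), NOP = c(4, 19),
                 OBT = c(0, 3), EXIT_DUR = c(0, 60), HR = c(45, 85),
                 RR = c(10, 25), TO_BED = c(0, 360), ARISE = c(0, 360),
                 SNR = c(0, 1), WSA_DEEP = c(0, 1), WSA_AWAKE = c(0, 1),
                 WSA_REM = c(0, 1), WSA_LIGHT = c(0, 1),
                 DEEP_DUR = c(0, 16), AWAKE_DUR = c(0, 16),
                 REM_DUR = c(0, 16), LIGHT_DUR = c(0, 16),
                 SNT = c(0, 960))
  if (metric == "EXITS") return(seq(-0.5, 20.5, by = 1))
  r <- ranges[[metric]]
  if (is.null(r)) return(NULL)
  seq(r[1], r[2], length.out = 51)
}

#' Pairwise Hellinger distances between groups of nights
#'
#' Bins each metric on shared canonical edges (the filter-admissible range,
#' 50 equal-width bins; integer bins for exit counts) and computes the
#' Hellinger distance for every group pair. Cells based on a group with
#' fewer than 30 nights carry a warning flag.
#'
#' @param records night records carrying a `group` column (or supply
#'   `groups`, a vector aligned with the rows).
#' @param metrics metric column names to compare.
#' @param groups optional explicit group vector.
#' @return a `data.table`: `metric`, `group1`, `group2`, `distance`,
#'   `small_sample`.
#' @export
compare_groups <- function(records,
                           metrics = c("IBT", "EXITS", "EXIT_DUR", "OBT",
                                       "HR", "RR", "TO_BED", "ARISE"),
                           groups = records$group) {
  r <- as.data.table(records)
  if (is.null(groups)) stop("no group labels supplied")
  glev <- unique(as.character(groups))
  if (length(glev) < 2L) stop("need at least two groups")
  sizes <- table(as.character(groups))
  pairs <- utils::combn(glev, 2L)
  out <- rbindlist(lapply(metrics, function(mt) {
    edges <- default_bin_edges(mt)
    if (is.null(edges)) {
      v <- r[[mt]][is.finite(r[[mt]])]
      edges <- seq(min(v), max(v) + 1e-9, length.out = 51)
    }
    dists <- lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      P <- bin_metric(r[[mt]][groups == g1], edges, mt)
      Q <- bin_metric(r[[mt]][groups == g2], edges, mt)
      data.table(metric = mt, group1 = g1, group2 = g2,
                 distance = hellinger(P, Q),
                 small_sample = sizes[[g1]] < 30 || sizes[[g2]] < 30)
    })
    rbindlist(dists)
  }))
  out[]
}

#' Circular correlation between paired timing angles
#'
#' Fisher--Lee circular correlation coefficient between two angle vectors
#' (degrees), with a seed-reproducible percentile bootstrap confidence
#' interval. Used to quantify the association between going-to-bed and
#' arise times, which live on the circle rather than the line.
#'
#' @param theta,phi paired angle vectors in degrees (n >= 10).
#' @param n_boot bootstrap resamples for the percentile CI.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
circular_correlation <- function(theta, phi, n_boot = 1000, conf = 0.95,
                                 seed = 1L) {
  stopifnot(length(theta) == length(phi))
  n <- length(theta)
  if (n < 10) stop("need at least 10 paired angles")
  th <- theta * pi / 180
  ph <- phi * pi / 180
  r <- fisher_lee(th, ph)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    fisher_lee(th[i], ph[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- quantile(boots, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(r = r, ci_low = ci[1], ci_high = ci[2], n = n)
}

## Fisher-Lee coefficient via the O(n) complex-sum identity:
##   sum_{i,j} sin(a_i - a_j) sin(b_i - b_j)
##     = (|sum e^{i(a-b)}|^2 - |sum e^{i(a+b)}|^2) / 2
##   sum_{i,j} sin^2(a_i - a_j) = (n^2 - |sum e^{2ia}|^2) / 2
fisher_lee <- function(a, b) {
  n <- length(a)
  mod2 <- function(x) Mod(sum(exp(1i * x)))^2
  num <- (mod2(a - b) - mod2(a + b)) / 2
  d1 <- (n^2 - mod2(2 * a)) / 2
  d2 <- (n^2 - mod2(2 * b)) / 2
  if (d1 <= 0 || d2 <= 0) return(NA_real_)
  num / sqrt(d1 * d2)
}

#' Propensity-score matching of cases to population controls
#'
#' Fits a logistic regression of case status on the covariates, then greedily
#' matches each case (in stable id order) with up to `ratio` controls having
#' the nearest propensity scores, without replacement; ties break by control
#' id. Reports covariate balance as standardized mean differences before and
#' after matching.
#'
#' @param cases,pool data.frames with an `participant_id` column and the
#'   covariate columns; the pool must be disjoint from the cases.
#' @param covariates covariate column names (default age and sex).
#' @param ratio maximum controls per case.
#' @return an object of class `match_result`: `matches` (case id, control id,
#'   propensity difference), `model` coefficients, `balance` table, and ids
#'   of unmatched cases.
#' @export
propensity_match <- function(cases, pool, covariates = c("age", "sex"),
                             ratio = 10L) {
  cases <- as.data.table(cases)
  pool <- as.data.table(pool)
  if (!nrow(pool)) stop("empty control pool")
  if (any(pool$participant_id %in% cases$participant_id)) {
    stop("pool must be disjoint from cases")
  }
  all_dt <- rbind(cases[, c("participant_id", covariates), with = FALSE],
                  pool[, c("participant_id", covariates), with = FALSE])
  y <- c(rep(1L, nrow(cases)), rep(0L, nrow(pool)))
  fml <- stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  fit <- glm(fml, data = cbind(all_dt, y = y), family = binomial())
  ps <- predict(fit, type = "response")
  ps_case <- ps[seq_len(nrow(cases))]
  ps_pool <- ps[-seq_len(nrow(cases))]

  ord <- order(cases$participant_id)
  available <- rep(TRUE, nrow(pool))
  match_list <- vector("list", nrow(cases))
  for (ii in ord) {
    d <- abs(ps_pool - ps_case[ii])
    cand <- which(available)
    if (!length(cand)) break
    o <- cand[order(d[cand], pool$participant_id[cand])]
    take <- head(o, ratio)
    available[take] <- FALSE
    if (length(take)) {
      match_list[[ii]] <- data.table(case_id = cases$participant_id[ii],
                                     control_id = pool$participant_id[take],
                                     ps_diff = d[take])
    }
  }
  matches <- rbindlist(match_list[!vapply(match_list, is.null, logical(1))])
  unmatched <- setdiff(cases$participant_id, matches$case_id)

  smd <- function(xa, xb) {
    s <- sqrt((var(xa) + var(xb)) / 2)
    if (!is.finite(s) || s == 0) return(0)
    (mean(xa) - mean(xb)) / s
  }
  bal <- rbindlist(lapply(covariates, function(cv) {
    pre <- smd(cases[[cv]], pool[[cv]])
    sel <- pool$participant_id %in% matches$control_id
    post <- if (any(sel)) smd(cases[[cv]], pool[[cv]][sel]) else NA_real_
    data.table(covariate = cv, smd_pre = pre, smd_post = post)
  }))
  structure(list(matches = matches, unmatched = unmatched,
                 coefficients = stats::coef(fit), balance = bal),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result>\n")
  cat(sprintf("  %d cases matched (%d unmatched), %d controls used\n",
              length(unique(x$matches$case_id)), length(x$unmatched),
              nrow(x$matches)))
  print(x$balance)
  invisible(x)
}

utils::globalVariables(c("group1", "group2", "distance", "small_sample",
                         "case_id", "control_id", "ps_diff", "covariate"))
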