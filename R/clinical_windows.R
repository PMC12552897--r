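## 90-day pre-assessment sleep-state profiles, their clustering into
## assessment states and participants into groups, and heteroscedasticity-
## robust group-effect testing (Welch ANOVA, Games-Howell, Levene,
## Bonferroni).

#' Build 90-day pre-assessment window profiles
#'
#' For each clinical assessment, summarizes the half-open 90-day window
#' `[date - 90, date)` preceding it: the proportion of labelled nights in
#' each bed-occupancy phenotype, mean behavioral metrics, and the assessment
#' scores (one column per scale). Assessments with fewer than `min_days`
#' distinct labelled nights in the window are excluded (logged in attribute
#' `excluded`).
#'
#' @param assessments table with `participant_id`, `assessment_date`,
#'   `scale`, `score`.
#' @param night_labels night records with `participant_id`, `night_date`, a
#'   `label` column (phenotype), and optionally behavioral metric columns
#'   (IBT, OBT, EXITS, EXIT_DUR).
#' @param window_days window length, default 90.
#' @param min_days minimum labelled nights required, default 15.
#' @return a `data.table`, one row per retained (participant, date):
#'   `n_nights`, `prop_<k>` proportion columns, mean metrics, scale score
#'   columns.
#' @export
build_windows <- function(assessments, night_labels, window_days = 90L,
                          min_days = 15L) {
  a <- as.data.table(assessments)
  nl <- as.data.table(night_labels)
  stopifnot(all(c("participant_id", "night_date", "label") %in% names(nl)))
  klev <- sort(unique(nl$label))
  metric_cols <- intersect(c("IBT", "OBT", "EXITS", "EXIT_DUR"), names(nl))
  visits <- unique(a[, .(participant_id, assessment_date)])
  rows <- lapply(seq_len(nrow(visits)), function(i) {
    pid <- visits$participant_id[i]
    ad <- visits$assessment_date[i]
    w <- nl[participant_id == pid & night_date >= ad - window_days &
              night_date < ad]
    nn <- length(unique(w$night_date))
    props <- as.numeric(table(factor(w$label, levels = klev))) /
      max(nrow(w), 1L)
    means <- if (length(metric_cols)) w[, lapply(.SD, mean),
                                        .SDcols = metric_cols]
             else NULL
    out <- data.table(participant_id = pid, assessment_date = ad,
                      n_nights = nn)
    for (j in seq_along(klev)) out[, (paste0("prop_", klev[j])) := props[j]]
    if (!is.null(means)) out <- cbind(out, means)
    out
  })
  prof <- rbindlist(rows)
  scores <- dcast(a, participant_id + assessment_date ~ scale,
                  value.var = "score", fun.aggregate = mean)
  prof <- merge(prof, scores, by = c("participant_id", "assessment_date"),
                all.x = TRUE)
  keep <- prof$n_nights >= min_days
  excluded <- prof[!keep, .(participant_id, assessment_date, n_nights)]
  out <- prof[keep]
  setattr(out, "excluded", excluded)
  setattr(out, "phenotypes", klev)
  out[]
}

## pairwise Hellinger distances between rows of a proportion matrix,
## via the sqrt embedding: H = dist(sqrt(P)) / sqrt(2)
hellinger_dist <- function(P) {
  dist(sqrt(P)) / sqrt(2)
}

proportion_matrix <- function(profiles) {
  pc <- grep("^prop_", names(profiles), value = TRUE)
  if (!length(pc)) stop("no proportion columns (prop_*) found")
  as.matrix(as.data.table(profiles)[, pc, with = FALSE])
}

#' Cluster assessment windows into assessment states
#'
#' Ward-linkage hierarchical clustering of the pairwise Hellinger distances
#' between window sleep-state proportion vectors; the number of states is
#' selected by the minimum Davies--Bouldin score over `k_range` (computed in
#' the square-root embedding in which the Hellinger distance is Euclidean).
#'
#' @param profiles output of [build_windows()].
#' @param k_range candidate cluster counts.
#' @return list of class `window_clustering`: `labels`, `k`, `tree`,
#'   `selection`.
#' @export
cluster_windows <- function(profiles, k_range = 2:8) {
  P <- proportion_matrix(profiles)
  if (nrow(P) < 8L) stop("need at least 8 window profiles")
  d <- hellinger_dist(P)
  tree <- hclust(d, method = "ward.D2")
  emb <- sqrt(P)
  scores <- vapply(k_range, function(k) davies_bouldin(emb, cutree(tree, k)),
                   numeric(1))
  k <- k_range[which.min(scores)]
  structure(list(labels = cutree(tree, k), k = k, tree = tree,
                 selection = data.table(k = k_range,
                                        davies_bouldin = scores)),
            class = "window_clustering")
}

#' Cluster participants into groups by their phenotype mix
#'
#' Complete-linkage hierarchical clustering of pairwise Hellinger distances
#' between per-participant sleep-state proportion vectors; the number of
#' groups is selected by the maximum mean silhouette width over `k_range`.
#' A maximum silhouette below 0.25 is flagged as weak structure (the usual
#' reading of silhouette widths under which values below 0.25 indicate no
#' substantial clustering).
#'
#' @param proportions matrix (participants x phenotypes) of proportions, or
#'   a data.frame with `prop_*` columns; rows must sum to 1.
#' @param k_range candidate group counts.
#' @return list of class `participant_clustering`: `labels`, `k`, `tree`,
#'   `selection` (silhouette per K), `weak_structure`.
#' @export
cluster_participants <- function(proportions, k_range = 2:8) {
  P <- if (is.matrix(proportions)) proportions
       else proportion_matrix(proportions)
  if (nrow(P) < 4L) stop("need at least 4 participants")
  k_range <- k_range[k_range < nrow(P)]
  d <- hellinger_dist(P)
  tree <- hclust(d, method = "complete")
  scores <- vapply(k_range, function(k) {
    mean(cluster::silhouette(cutree(tree, k), d)[, "sil_width"])
  }, numeric(1))
  k <- k_range[which.max(scores)]
  structure(list(labels = cutree(tree, k), k = k, tree = tree,
                 selection = data.table(k = k_range, silhouette = scores),
                 weak_structure = max(scores) < 0.25),
            class = "participant_clustering")
}

## Welch F closed form with a variance floor for degenerate (zero-variance)
## groups; the ordinary path delegates to stats::oneway.test
welch_f_floored <- function(values, groups, floor = 1e-12) {
  g <- split(values, groups)
  ni <- lengths(g)
  mi <- vapply(g, mean, numeric(1))
  vi <- pmax(vapply(g, var, numeric(1)), floor)
  K <- length(g)
  wi <- ni / vi
  W <- sum(wi)
  mw <- sum(wi * mi) / W
  A <- sum(wi * (mi - mw)^2) / (K - 1)
  B <- sum((1 - wi / W)^2 / (ni - 1))
  f <- A / (1 + 2 * (K - 2) * B / (K^2 - 1))
  df2 <- (K^2 - 1) / (3 * B)
  list(statistic = f, df1 = K - 1, df2 = df2,
       p = pf(f, K - 1, df2, lower.tail = FALSE))
}

## classic Levene test: one-way ANOVA on absolute deviations from group means
levene_test <- function(values, groups) {
  z <- abs(values - stats::ave(values, groups))
  a <- anova(aov(z ~ factor(groups)))
  list(statistic = a$`F value`[1], p = a$`Pr(>F)`[1])
}

## Games-Howell post hoc pairwise comparisons
games_howell <- function(values, groups) {
  g <- split(values, groups)
  lev <- names(g)
  K <- length(g)
  ni <- lengths(g)
  mi <- vapply(g, mean, numeric(1))
  vi <- vapply(g, var, numeric(1))
  pairs <- utils::combn(K, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(jj) {
    i <- pairs[1, jj]; j <- pairs[2, jj]
    se2 <- vi[i] / ni[i] + vi[j] / ni[j]
    t_stat <- (mi[i] - mi[j]) / sqrt(se2)
    df <- se2^2 / ((vi[i] / ni[i])^2 / (ni[i] - 1) +
                     (vi[j] / ni[j])^2 / (ni[j] - 1))
    p <- ptukey(abs(t_stat) * sqrt(2), nmeans = K, df = df,
                lower.tail = FALSE)
    sp <- sqrt(((ni[i] - 1) * vi[i] + (ni[j] - 1) * vi[j]) /
                 (ni[i] + ni[j] - 2))
    d <- (mi[i] - mi[j]) / sp
    gg <- d * (1 - 3 / (4 * (ni[i] + ni[j]) - 9))
    data.table(group1 = lev[i], group2 = lev[j],
               mean_diff = mi[i] - mi[j], t = t_stat, df = df,
               hedges_g = gg, p_adj = p)
  })
  rbindlist(rows)
}

#' Test group effects on outcome variables
#'
#' For each outcome: Welch's heteroscedasticity-robust ANOVA (with eta^2
#' effect size), a Levene homoscedasticity check, Games--Howell post hoc
#' pairwise comparisons, and Bonferroni correction of the omnibus p-values
#' across the outcome family. Groups with zero variance are handled with a
#' variance floor of 1e-12 and flagged.
#'
#' @param data data.frame with the outcome columns and a group column.
#' @param outcomes outcome column names (the Bonferroni family).
#' @param group name of the group column.
#' @param alpha significance level for the significance flags.
#' @return a named list of `group_effect_report` objects, one per outcome.
#' @export
group_effects <- function(data, outcomes, group = "group", alpha = 0.05) {
  d <- as.data.table(data)
  fam <- length(outcomes)
  reports <- lapply(outcomes, function(oc) {
    ok <- is.finite(d[[oc]])
    v <- d[[oc]][ok]
    gr <- factor(d[[group]][ok])
    cnt <- table(gr)
    if (length(cnt) < 2L || any(cnt < 3L)) {
      stop("outcome ", oc, ": need >= 2 groups with >= 3 observations each")
    }
    vars <- vapply(split(v, gr), var, numeric(1))
    degenerate <- any(vars <= 0)
    if (degenerate) {
      wf <- welch_f_floored(v, gr)
    } else {
      ow <- oneway.test(v ~ gr, var.equal = FALSE)
      wf <- list(statistic = unname(ow$statistic), df1 = unname(ow$parameter[1]),
                 df2 = unname(ow$parameter[2]), p = ow$p.value)
    }
    grand <- mean(v)
    ssb <- sum(tapply(v, gr, function(x) length(x) * (mean(x) - grand)^2))
    sst <- sum((v - grand)^2)
    lv <- levene_test(v, gr)
    gh <- games_howell(v, gr)
    structure(list(outcome = oc, F = wf$statistic, df1 = wf$df1,
                   df2 = wf$df2, p = wf$p,
                   p_bonferroni = min(wf$p * fam, 1),
                   significant = min(wf$p * fam, 1) < alpha,
                   eta2 = ssb / sst,
                   levene_F = lv$statistic, levene_p = lv$p,
                   pairwise = gh, degenerate_variance = degenerate),
              class = "group_effect_report")
  })
  names(reports) <- outcomes
  reports
}

#' @export
print.group_effect_report <- function(x, ...) {
  cat(sprintf("<group_effect_report> %s: Welch F(%.0f, %.1f) = %.3f, p = %.3g (Bonferroni %.3g), eta2 = %.3f\n",
              x$outcome, x$df1, x$df2, x$F, x$p, x$p_bonferroni, x$eta2))
  cat(sprintf("  Levene F = %.3f (p = %.3g)%s\n", x$levene_F, x$levene_p,
              if (x$degenerate_variance) " [zero-variance group, floored]" else ""))
  print(x$pairwise)
  invisible(x)
}

utils::globalVariables(c("silhouette", "mean_diff", "hedges_g", "p_adj"))
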