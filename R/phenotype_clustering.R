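## Night-level bed-occupancy phenotypes: 15-minute occupancy aggregates, the
## combined Jaccard/Euclidean night dissimilarity, Ward clustering with
## Davies-Bouldin model selection, duration-ordered relabelling, and the
## leave-one-group-out state classifier that projects the phenotypes onto
## new nights.

#' Aggregate occupancy grids to 15-minute bins
#'
#' Collapses each standard 1440-cell noon-to-noon grid to 96 counts of
#' occupied minutes per quarter hour, plus the binary non-occupancy mask
#' (`mask = 1` iff the bin holds no occupied minute). Grids of nonstandard
#' length (daylight-saving windows) are excluded with a diagnostic.
#'
#' @param grids output of [resample_occupancy()].
#' @return an object of class `night_aggregates`: `keys` (participant, night),
#'   `bins` (nights x 96 count matrix), `mask` (nights x 96 binary matrix);
#'   attribute `excluded` lists dropped nonstandard windows.
#' @export
aggregate_15min <- function(grids) {
  std <- grids$len == 1440L
  excluded <- grids[!std, .(participant_id, night_date, len)]
  g <- grids[std]
  if (!nrow(g)) stop("no standard-length grids to aggregate")
  occ <- matrix(unlist(g$occupied), nrow = nrow(g), byrow = TRUE)
  grp <- rep(seq_len(96), each = 15)
  bins <- t(apply(occ, 1L, function(v) {
    as.vector(rowsum(v, grp))
  }))
  mask <- (bins == 0) + 0L
  structure(list(keys = g[, .(participant_id, night_date)],
                 bins = bins, mask = mask),
            class = "night_aggregates", excluded = excluded)
}

## Jaccard distance between non-occupancy masks of two nights:
## 1 - |X & Y| / |X | Y|, and 0 when both masks are empty.
jaccard_mask <- function(x, y) {
  u <- sum(x | y)
  if (u == 0) return(0)
  1 - sum(x & y) / u
}

#' Pairwise night dissimilarities
#'
#' Computes the combined night-to-night dissimilarity: the Jaccard distance
#' between binary non-occupancy masks and the Euclidean distance between the
#' 15-minute occupancy counts, each min-max normalized over the dataset and
#' averaged with equal weight. The normalization constants are returned so
#' new nights can be projected consistently.
#'
#' @param agg a [aggregate_15min()] object.
#' @return list: `combined` (dist object in `[0, 1]`), `jaccard`, `euclid`
#'   (raw dist objects), `norm` (min/max constants).
#' @export
night_distance_matrix <- function(agg) {
  m <- agg$mask
  n <- nrow(m)
  ## |X & Y| and |X | Y| via cross products on the binary masks
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  J <- 1 - inter / uni
  J[uni == 0] <- 0
  diag(J) <- 0
  E <- as.matrix(dist(agg$bins))
  norm <- list(j_min = min(J[upper.tri(J)]), j_max = max(J[upper.tri(J)]),
               e_min = min(E[upper.tri(E)]), e_max = max(E[upper.tri(E)]))
  C <- (rescale01(J, norm$j_min, norm$j_max) +
          rescale01(E, norm$e_min, norm$e_max)) / 2
  diag(C) <- 0
  list(combined = as.dist(C), jaccard = as.dist(J), euclid = as.dist(E),
       norm = norm)
}

rescale01 <- function(x, lo, hi) {
  if (hi <= lo) return(x * 0)
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Combined dissimilarity between two nights
#'
#' @param a,b integer vectors of 96 occupied-minute counts.
#' @param norm normalization constants from [night_distance_matrix()]; when
#'   omitted the raw Jaccard/Euclidean average is returned.
#' @return scalar dissimilarity.
#' @export
night_distance <- function(a, b, norm = NULL) {
  stopifnot(length(a) == length(b))
  J <- jaccard_mask(a == 0, b == 0)
  E <- sqrt(sum((a - b)^2))
  if (is.null(norm)) return((J + E) / 2)
  (rescale01(J, norm$j_min, norm$j_max) +
      rescale01(E, norm$e_min, norm$e_max)) / 2
}

## Davies-Bouldin index of a labelled point set (lower is better)
davies_bouldin <- function(x, labels) {
  lev <- sort(unique(labels))
  cent <- t(vapply(lev, function(l) colMeans(x[labels == l, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_along(lev), function(i) {
    xi <- x[labels == lev[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2L, cent[i, ])^2)))
  }, numeric(1))
  D <- as.matrix(dist(cent))
  db <- vapply(seq_along(lev), function(i) {
    r <- (s[i] + s[-i]) / D[i, -i]
    max(r)
  }, numeric(1))
  mean(db)
}

#' Cluster nights into bed-occupancy phenotypes
#'
#' Hierarchical agglomerative clustering (Ward linkage) of the combined
#' Jaccard/Euclidean night dissimilarity; the number of clusters is selected
#' by the minimum Davies--Bouldin score over `k_range`, and cluster labels
#' are renumbered 1..K by descending mean occupied minutes (see
#' [relabel_by_duration()]). Deterministic given the input.
#'
#' @param agg a [aggregate_15min()] object.
#' @param k_range candidate cluster counts.
#' @return an object of class `sleep_wake_clustering`: `labels`, `k`,
#'   `tree` (hclust), `selection` (Davies--Bouldin per candidate K),
#'   `cluster_minutes` (mean occupied minutes per label), `norm`
#'   (dissimilarity normalization constants), `keys`.
#' @export
cluster_nights <- function(agg, k_range = 2:10) {
  n <- nrow(agg$bins)
  if (n < max(k_range)) stop("fewer nights than the largest candidate K")
  dm <- night_distance_matrix(agg)
  if (max(dm$combined) <= 0) {
    stop("degenerate input: all nights identical (zero-variance distances)")
  }
  tree <- hclust(dm$combined, method = "ward.D2")
  scores <- vapply(k_range, function(k) {
    davies_bouldin(agg$bins, cutree(tree, k))
  }, numeric(1))
  k <- k_range[which.min(scores)]
  labels <- cutree(tree, k)
  cl <- structure(list(labels = labels, k = k, tree = tree,
                       selection = data.table(k = k_range, davies_bouldin = scores),
                       cluster_minutes = NULL, norm = dm$norm,
                       keys = agg$keys),
                  class = "sleep_wake_clustering")
  relabel_by_duration(cl, agg)
}

#' Renumber clusters by mean bed-occupancy duration
#'
#' Reassigns cluster labels 1..K in order of descending mean occupied
#' minutes, independent of the clustering order; ties break by cluster size
#' (larger first) then by original label. Idempotent.
#'
#' @param clustering a `sleep_wake_clustering`.
#' @param agg the [aggregate_15min()] object the clustering was fitted on.
#' @return the clustering with relabelled `labels` and `cluster_minutes`.
#' @export
relabel_by_duration <- function(clustering, agg) {
  lab <- clustering$labels
  lev <- sort(unique(lab))
  minutes <- vapply(lev, function(l) mean(rowSums(agg$bins[lab == l, ,
                                                           drop = FALSE])),
                    numeric(1))
  sizes <- vapply(lev, function(l) sum(lab == l), numeric(1))
  ord <- order(-minutes, -sizes, lev)
  new_of_old <- integer(length(lev))
  new_of_old[ord] <- seq_along(lev)
  clustering$labels <- new_of_old[match(lab, lev)]
  clustering$cluster_minutes <- minutes[ord]
  clustering
}

#' @export
print.sleep_wake_clustering <- function(x, ...) {
  cat(sprintf("<sleep_wake_clustering> %d nights in %d clusters\n",
              length(x$labels), x$k))
  tab <- table(x$labels)
  for (l in names(tab)) {
    cat(sprintf("  cluster %s: %4d nights, mean occupancy %.0f min\n",
                l, tab[[l]], x$cluster_minutes[as.integer(l)]))
  }
  invisible(x)
}

#' Train the night-state classifier with leave-one-group-out validation
#'
#' Fits an interpretable additive boosted multiclass model predicting each
#' night's bed-occupancy phenotype from seven nightly metrics (IBT, TO_BED,
#' ARISE, NOP, OBT, EXITS, EXIT_DUR), evaluated by leave-one-group-out
#' cross-validation with participants as groups: the model is trained on all
#' participants but one and tested on the held-out participant's nights.
#' Folds whose training data lack a class are skipped with a diagnostic.
#' The final model is refit on all data.
#'
#' @param records night records containing the feature columns.
#' @param labels integer phenotype labels aligned with the rows.
#' @param groups participant ids aligned with the rows.
#' @param nrounds,eta boosting hyperparameters.
#' @return an object of class `state_classifier`: final `model`, per-fold
#'   `cv` metrics (accuracy, macro precision/sensitivity/F1), `macro`
#'   averages, `classes`, `skipped_folds`.
#' @export
train_state_classifier <- function(records, labels, groups,
                                   nrounds = 150L, eta = 0.15) {
  r <- as.data.table(records)
  x <- as.matrix(r[, STATE_FEATURES, with = FALSE])
  y <- factor(labels)
  if (length(unique(groups)) < 3L) stop("need at least 3 groups for LOGO CV")
  folds <- unique(groups)
  cv_rows <- list(); skipped <- character()
  for (g in folds) {
    tr <- groups != g
    if (length(unique(y[tr])) < nlevels(y)) {
      skipped <- c(skipped, as.character(g))
      next
    }
    fit <- fit_additive_boost(x[tr, , drop = FALSE], y[tr],
                              nrounds = nrounds, eta = eta)
    prob <- predict(fit, x[!tr, , drop = FALSE])
    pred <- colnames(prob)[max.col(prob, ties.method = "first")]
    mm <- multiclass_metrics(as.character(y[!tr]), pred, levels(y))
    cv_rows[[length(cv_rows) + 1L]] <-
      data.table(group = as.character(g), n = sum(!tr),
                 accuracy = mm$accuracy, precision = mm$precision,
                 sensitivity = mm$sensitivity, f1 = mm$f1)
  }
  cv <- rbindlist(cv_rows)
  final <- fit_additive_boost(x, y, nrounds = nrounds, eta = eta)
  structure(list(model = final, classes = levels(y), cv = cv,
                 macro = cv[, .(accuracy = mean(accuracy),
                                precision = mean(precision),
                                sensitivity = mean(sensitivity),
                                f1 = mean(f1))],
                 skipped_folds = skipped, features = STATE_FEATURES),
            class = "state_classifier")
}

## macro-averaged multiclass metrics (classes absent from both truth and
## prediction contribute nothing; empty-precision classes count as 0)
multiclass_metrics <- function(truth, pred, classes) {
  per <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(rec) && prec + rec > 0) 2 * prec * rec / (prec + rec)
          else if (!is.na(rec)) 0 else NA_real_
    c(prec, rec, f1)
  }, numeric(3))
  present <- !is.na(per[2, ])
  list(accuracy = mean(truth == pred),
       precision = mean(per[1, present]),
       sensitivity = mean(per[2, present]),
       f1 = mean(per[3, present]))
}

#' @export
print.state_classifier <- function(x, ...) {
  cat(sprintf("<state_classifier> %d classes, %d LOGO folds\n",
              length(x$classes), nrow(x$cv)))
  cat(sprintf("  macro: accuracy %.3f, precision %.3f, sensitivity %.3f, F1 %.3f\n",
              x$macro$accuracy, x$macro$precision, x$macro$sensitivity,
              x$macro$f1))
  invisible(x)
}

#' Assign phenotype labels to new nights
#'
#' @param classifier a [train_state_classifier()] object.
#' @param records night records with the feature columns; rows with missing
#'   features are skipped with a diagnostic.
#' @return integer labels (NA for skipped rows); attribute `probabilities`
#'   holds the per-class probability matrix.
#' @export
assign_states <- function(classifier, records) {
  r <- as.data.table(records)
  x <- as.matrix(r[, classifier$features, with = FALSE])
  ok <- complete.cases(x)
  out <- rep(NA_integer_, nrow(x))
  probs <- matrix(NA_real_, nrow(x), length(classifier$classes))
  colnames(probs) <- classifier$classes
  if (any(ok)) {
    p <- predict(classifier$model, x[ok, , drop = FALSE])
    out[ok] <- as.integer(colnames(p)[max.col(p, ties.method = "first")])
    probs[ok, ] <- p
  }
  if (any(!ok)) message(sum(!ok), " night(s) skipped: missing features")
  attr(out, "probabilities") <- probs
  out
}

utils::globalVariables(c("len", "accuracy", "precision", "sensitivity", "f1",
                         "davies_bouldin"))
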