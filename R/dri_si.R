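## The nightly sleep-disturbance index: an averaged ensemble of interpretable
## additive boosted binary classifiers trained under a multi-level splitting
## protocol (participant-level naive hold-out, per-participant 30-day horizon
## hold-out, and per-member stratified bootstrap + quasi-random temporal
## subsampling + random under-sampling).

round_half_down <- function(x) ceiling(x - 0.5)

#' Multi-level train/test splitting of cohort nights
#'
#' Reserves (1) a participant-level naive test set: a stratified fraction of
#' participants per class whose nights never enter training, and (2) a
#' horizon test set: each remaining participant's final `horizon_days` of
#' observations, probing temporal generalization. Remaining nights form the
#' training universe. Participants with too few nights to spare a horizon
#' tail (fewer than `horizon_days + 1` distinct nights) contribute all
#' nights to training (logged in `short_participants`).
#'
#' @param nights night records with `participant_id`, `night_date` and a
#'   binary `label` column (1 = case) constant within participant.
#' @param naive_fraction participant fraction per class held out
#'   (rounded half-down).
#' @param horizon_days length of the per-participant horizon tail.
#' @param seed integer; the participant draw is reproducible.
#' @return an object of class `split_plan`: the input with a `partition`
#'   column (`naive`, `horizon`, `train`), plus `naive_participants` and
#'   `short_participants`.
#' @export
split_multilevel <- function(nights, naive_fraction = 0.1, horizon_days = 30L,
                             seed = 1L) {
  n <- as.data.table(nights)
  stopifnot(all(c("participant_id", "night_date", "label") %in% names(n)))
  pts <- unique(n[, .(participant_id, label)])
  if (anyDuplicated(pts$participant_id)) {
    stop("label must be constant within participant")
  }
  set.seed(seed)
  naive_ids <- unlist(lapply(split(pts$participant_id, pts$label), function(ids) {
    ids <- sort(ids)
    k <- round_half_down(length(ids) * naive_fraction)
    if (k > 0) sample(ids, k) else character()
  }))
  n[, partition := "train"]
  n[participant_id %in% naive_ids, partition := "naive"]
  rest <- n[partition == "train"]
  info <- rest[, .(n_nights = uniqueN(night_date), last = max(night_date)),
               by = participant_id]
  short <- info[n_nights < horizon_days + 1L, participant_id]
  cut <- info[!participant_id %in% short]
  if (nrow(cut)) {
    n[cut, on = "participant_id",
      partition := ifelse(partition == "train" &
                            night_date > i.last - horizon_days,
                          "horizon", partition)]
  }
  structure(list(nights = n, naive_participants = sort(naive_ids),
                 short_participants = short, seed = seed,
                 naive_fraction = naive_fraction,
                 horizon_days = horizon_days),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  tab <- table(x$nights$partition)
  cat("<split_plan>\n")
  cat(sprintf("  naive: %d participants / %d nights; horizon: %d nights; train: %d nights\n",
              length(x$naive_participants),
              if ("naive" %in% names(tab)) tab[["naive"]] else 0L,
              if ("horizon" %in% names(tab)) tab[["horizon"]] else 0L,
              if ("train" %in% names(tab)) tab[["train"]] else 0L))
  if (length(x$short_participants)) {
    cat(sprintf("  %d participant(s) too short for a horizon tail (all nights -> train)\n",
                length(x$short_participants)))
  }
  invisible(x)
}

## Quasi-random temporal subsample of one participant's nights: the timeline
## is split into `blocks` equal blocks and one night per block per pass is
## picked at the van der Corput position, spreading picks over the timeline
## while preserving temporal order.
temporal_subsample <- function(n_nights, blocks = 10L, passes = 3L,
                               start = 0L) {
  if (n_nights <= blocks * passes) return(seq_len(n_nights))
  bounds <- floor(seq(0L, n_nights, length.out = blocks + 1L))
  picks <- unlist(lapply(seq_len(blocks), function(b) {
    m <- bounds[b + 1L] - bounds[b]
    if (m <= 0L) return(integer())
    u <- van_der_corput(start + seq_len(passes) - 1L)
    bounds[b] + unique(pmin(floor(u * m) + 1L, m))
  }))
  sort(unique(picks))
}

#' Fit one ensemble member
#'
#' One iteration of the iterative fitting protocol: a stratified bootstrap
#' sample of participants is drawn within each class; each sampled
#' participant's nights are subsampled by the quasi-random temporal scheme
#' (10 timeline blocks, one van der Corput pick per block per pass); the
#' majority class is randomly under-sampled to 1:1; and an interpretable
#' additive boosted binary classifier is fitted. Nights of sampled
#' participants that were not selected are split evenly into internal test
#' and validation subsets whose AUCs are recorded.
#'
#' @param train night records (training universe) with `label` and the
#'   feature columns.
#' @param iteration_seed integer seed for this member.
#' @param passes temporal-sampling passes per block.
#' @param nrounds,eta boosting hyperparameters.
#' @return list: fitted `model`, `seed`, `internal_test_auc`,
#'   `internal_validation_auc`, `n_train`.
#' @export
fit_iteration <- function(train, iteration_seed, passes = 3L,
                          nrounds = 200L, eta = 0.1) {
  tr <- as.data.table(train)
  set.seed(iteration_seed)
  pts <- unique(tr[, .(participant_id, label)])
  boot <- unlist(lapply(split(pts$participant_id, pts$label), function(ids) {
    sample(ids, length(ids), replace = TRUE)
  }))
  setkey(tr, participant_id)
  sel_rows <- vector("list", length(boot))
  for (i in seq_along(boot)) {
    rows <- tr[.(boot[i]), which = TRUE]
    rows <- rows[order(tr$night_date[rows])]
    start <- sample.int(1024L, 1L)
    sel <- temporal_subsample(length(rows), passes = passes, start = start)
    sel_rows[[i]] <- rows[sel]
  }
  sel_all <- unlist(sel_rows)
  dat <- tr[sel_all]
  ## random under-sampling of the majority class to parity
  tab <- table(dat$label)
  if (length(tab) < 2L || any(tab == 0L)) {
    stop("a class is empty after sampling; use a different iteration seed")
  }
  n_min <- min(tab)
  keep <- unlist(lapply(split(seq_len(nrow(dat)), dat$label), function(ix) {
    if (length(ix) > n_min) sample(ix, n_min) else ix
  }))
  dat <- dat[sort(keep)]
  x <- as.matrix(dat[, DRI_FEATURES, with = FALSE])
  model <- fit_additive_boost(x, dat$label, nrounds = nrounds, eta = eta,
                              seed = iteration_seed)
  ## internal test / validation: unsampled nights of the sampled participants
  oob <- tr[setdiff(tr[.(unique(boot)), which = TRUE], sel_all)]
  it_auc <- iv_auc <- NA_real_
  if (nrow(oob) > 10L && length(unique(oob$label)) == 2L) {
    half <- sample(c(TRUE, FALSE), nrow(oob), replace = TRUE)
    sc <- predict(model, as.matrix(oob[, DRI_FEATURES, with = FALSE]))
    if (length(unique(oob$label[half])) == 2L) {
      it_auc <- auc_fast(oob$label[half], sc[half])
    }
    if (length(unique(oob$label[!half])) == 2L) {
      iv_auc <- auc_fast(oob$label[!half], sc[!half])
    }
  }
  list(model = model, seed = iteration_seed, internal_test_auc = it_auc,
       internal_validation_auc = iv_auc, n_train = nrow(dat),
       participants = sort(unique(boot)))
}

## rank-based AUC (equivalent to the Wilcoxon statistic)
auc_fast <- function(y, s) {
  y <- as.integer(y)
  r <- rank(s)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' A constant-score pseudo-member
#'
#' Produces a member whose model predicts the same score for every night;
#' useful for reasoning about the averaging merge rule (adding a 0.5 member
#' shrinks every ensemble score toward 0.5).
#'
#' @param score the constant probability.
#' @return a member usable in [merge_ensemble()].
#' @export
constant_member <- function(score = 0.5) {
  list(model = structure(list(score = score), class = "constant_score"),
       seed = NA_integer_, internal_test_auc = NA_real_,
       internal_validation_auc = NA_real_, n_train = 0L,
       participants = character())
}

#' @export
predict.constant_score <- function(object, x, ...) {
  rep(object$score, nrow(as.matrix(x)))
}

#' Merge fitted members into the final averaged ensemble
#'
#' The ensemble's nightly score is the arithmetic mean of the member
#' probabilities for the case class, a calibrated value in `[0, 1]`.
#'
#' @param members list of [fit_iteration()] results.
#' @param dummy_members optional list of members trained on shuffled labels
#'   (the dummy baseline).
#' @return an object of class `dri_si_ensemble`.
#' @export
merge_ensemble <- function(members, dummy_members = NULL) {
  if (!length(members)) stop("need at least one member")
  structure(list(members = members, dummy_members = dummy_members,
                 features = DRI_FEATURES,
                 member_seeds = vapply(members, `[[`, numeric(1), "seed"),
                 merge_rule = "mean"),
            class = "dri_si_ensemble")
}

#' @export
print.dri_si_ensemble <- function(x, ...) {
  cat(sprintf("<dri_si_ensemble> %d members (merge: %s), %d features\n",
              length(x$members), x$merge_rule, length(x$features)))
  it <- vapply(x$members, `[[`, numeric(1), "internal_test_auc")
  iv <- vapply(x$members, `[[`, numeric(1), "internal_validation_auc")
  cat(sprintf("  internal test AUC %.3f +/- %.3f; validation AUC %.3f +/- %.3f\n",
              mean(it, na.rm = TRUE), sd(it, na.rm = TRUE),
              mean(iv, na.rm = TRUE), sd(iv, na.rm = TRUE)))
  invisible(x)
}

#' Score nights with the ensemble
#'
#' @param object a `dri_si_ensemble`.
#' @param records night records with the feature columns.
#' @param members which member set to use (`"ensemble"` or `"dummy"`).
#' @param ... unused.
#' @return numeric nightly scores in `[0, 1]`.
#' @export
predict.dri_si_ensemble <- function(object, records,
                                    members = c("ensemble", "dummy"), ...) {
  members <- match.arg(members)
  mm <- if (members == "dummy") object$dummy_members else object$members
  if (!length(mm)) stop("no ", members, " members available")
  x <- as.matrix(as.data.table(records)[, object$features, with = FALSE])
  scores <- rowMeans(vapply(mm, function(m) predict(m$model, x),
                            numeric(nrow(x))))
  scores
}

#' Train the full sleep-disturbance index ensemble
#'
#' Repeats [fit_iteration()] `n_members` times with derived per-member seeds
#' and merges the members by averaging. A dummy baseline of
#' `n_dummy` members is trained in parallel on label-shuffled copies of the
#' training universe with the identical algorithm.
#'
#' @param train training-universe night records (`label` + features).
#' @param n_members ensemble size (1000 at full scale; smaller for routine
#'   runs).
#' @param seed master seed; member seeds are derived with [child_seed()].
#' @param n_dummy dummy-baseline members.
#' @param ... passed to [fit_iteration()].
#' @return a `dri_si_ensemble`.
#' @export
train_dri_si <- function(train, n_members = 50L, seed = 1L,
                         n_dummy = n_members, ...) {
  tr <- as.data.table(train)
  members <- lapply(seq_len(n_members), function(i) {
    fit_iteration(tr, child_seed(seed, 1L, i), ...)
  })
  dummy <- NULL
  if (n_dummy > 0L) {
    dummy <- lapply(seq_len(n_dummy), function(i) {
      ds <- child_seed(seed, 2L, i)
      set.seed(ds)
      shuf <- copy(tr)
      shuf[, label := sample(label)]
      fit_iteration(shuf, child_seed(ds, 1L), ...)
    })
  }
  merge_ensemble(members, dummy)
}

threshold_metrics <- function(y, score, threshold = 0.5) {
  pred <- as.integer(score >= threshold)
  tp <- sum(y == 1L & pred == 1L); tn <- sum(y == 0L & pred == 0L)
  fp <- sum(y == 0L & pred == 1L); fn <- sum(y == 1L & pred == 0L)
  prec_pos <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec_pos) && !is.na(sens) && prec_pos + sens > 0) {
    2 * prec_pos * sens / (prec_pos + sens)
  } else NA_real_
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  list(sensitivity = sens, specificity = spec, precision_pos = prec_pos,
       precision_neg = prec_neg, f1 = f1, mcc = mcc)
}

#' Evaluate the ensemble on labelled nights
#'
#' Threshold-0.5 classification metrics (sensitivity, specificity, positive
#' and negative precision, F1, Matthews correlation) plus the threshold-free
#' AUC-ROC, for the ensemble and for the dummy baseline trained on shuffled
#' labels. Dummy metrics are the mean over the per-member metric values (the
#' null models are reported as a distribution across iterations, one dummy
#' per member, never merged -- a merged average of random score functions
#' does not converge to chance performance). Single-class inputs yield a
#' missing AUC with a diagnostic.
#'
#' @param ensemble a `dri_si_ensemble`.
#' @param records labelled night records (feature columns + `label`).
#' @param with_dummy also evaluate the dummy members.
#' @return an object of class `eval_report`: `metrics` and `dummy_metrics`
#'   one-row tables, `n`, `dataset`.
#' @export
evaluate_index <- function(ensemble, records, with_dummy = TRUE) {
  r <- as.data.table(records)
  y <- as.integer(r$label)
  single <- length(unique(y)) < 2L
  if (single) message("single-class input: AUC undefined")
  score_metrics <- function(sc) {
    tm <- threshold_metrics(y, sc)
    as.data.table(c(tm, list(auc = if (single) NA_real_ else
      auc_fast(y, sc))))
  }
  metrics <- score_metrics(predict(ensemble, r, members = "ensemble"))
  dummy <- NULL
  if (with_dummy && length(ensemble$dummy_members)) {
    x <- as.matrix(r[, ensemble$features, with = FALSE])
    per <- rbindlist(lapply(ensemble$dummy_members, function(m) {
      score_metrics(predict(m$model, x))
    }))
    dummy <- per[, lapply(.SD, mean, na.rm = TRUE)]
    setattr(dummy, "per_member", per)
  }
  structure(list(metrics = metrics, dummy_metrics = dummy, n = nrow(r)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d nights\n  ensemble: ", x$n))
  print(round(as.data.frame(x$metrics), 3), row.names = FALSE)
  if (!is.null(x$dummy_metrics)) {
    cat("  dummy baseline: ")
    print(round(as.data.frame(x$dummy_metrics), 3), row.names = FALSE)
  }
  invisible(x)
}

#' Permutation feature importance on held-out nights
#'
#' Randomly shuffles each feature's values and records the resulting drop in
#' the ensemble's F1 score, averaged over `n_repeats` shuffles; a large drop
#' marks a feature the index relies on.
#'
#' @param ensemble a `dri_si_ensemble`.
#' @param records held-out labelled night records.
#' @param n_repeats shuffles per feature.
#' @param seed integer; shuffles are reproducible.
#' @return a `data.table` (`feature`, `f1_drop`, `sd`), sorted by decreasing
#'   mean drop; attribute `baseline_f1` holds the unshuffled F1.
#' @export
permutation_importance <- function(ensemble, records, n_repeats = 10L,
                                   seed = 1L) {
  r <- as.data.table(records)
  y <- as.integer(r$label)
  x <- as.matrix(r[, ensemble$features, with = FALSE])
  score_f1 <- function(m) {
    sc <- rowMeans(vapply(ensemble$members,
                          function(mb) predict(mb$model, m),
                          numeric(nrow(m))))
    threshold_metrics(y, sc)$f1
  }
  base <- score_f1(x)
  rows <- lapply(seq_along(ensemble$features), function(j) {
    drops <- vapply(seq_len(n_repeats), function(rep) {
      set.seed(child_seed(seed, j, rep))
      xs <- x
      xs[, j] <- sample(xs[, j])
      base - score_f1(xs)
    }, numeric(1))
    data.table(feature = ensemble$features[j], f1_drop = mean(drops),
               sd = sd(drops))
  })
  out <- rbindlist(rows)
  setorder(out, -f1_drop)
  setattr(out, "baseline_f1", base)
  out[]
}

#' Categorize nightly scores into severity bands 1-6
#'
#' Equal-width sextile bins on `[0, 1]`, half-open `[l, u)` with the top bin
#' closed; category 6 is the most case-like. Monotone in the score.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @return integer categories in 1..6.
#' @export
categorize_scores <- function(scores) {
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]")
  }
  pmin(floor(scores * 6) + 1L, 6L)
}

utils::globalVariables(c("partition", "i.last", "f1_drop", "feature",
                         "uniqueN"))
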