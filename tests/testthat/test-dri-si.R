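## direct night-feature tables (no minute simulation) for the index module
fake_nights <- function(n_case = 10L, n_ctrl = 20L, nights = 40L,
                        signal = "EXITS", shift = 2, seed = 1L) {
  set.seed(seed)
  feats <- drisleep:::DRI_FEATURES
  mk <- function(ids, lab) {
    rbindlist(lapply(ids, function(id) {
      d <- data.table(participant_id = id,
                      night_date = as.Date("2021-01-01") + seq_len(nights) - 1,
                      label = lab)
      for (f in feats) d[, (f) := rnorm(nights)]
      if (!is.null(signal) && lab == 1L) {
        d[, (signal) := get(signal) + shift]
      }
      d
    }))
  }
  rbind(mk(sprintf("case%03d", seq_len(n_case)), 1L),
        mk(sprintf("ctrl%03d", seq_len(n_ctrl)), 0L))
}

test_that("the multi-level split holds out 10% of participants per class", {
  n <- fake_nights(83, 100, nights = 40, signal = NULL)
  plan <- split_multilevel(n, seed = 4)
  naive <- unique(plan$nights[partition == "naive",
                              .(participant_id, label)])
  expect_equal(sum(naive$label == 1), 8L)    # round-half-down of 8.3
  expect_equal(sum(naive$label == 0), 10L)
  ## no night in two partitions; naive participants contribute no train night
  expect_equal(nrow(plan$nights), nrow(n))
  tr_ids <- unique(plan$nights[partition != "naive", participant_id])
  expect_length(intersect(plan$naive_participants, tr_ids), 0)
  ## horizon nights are each remaining participant's last 30 days
  hz <- plan$nights[partition == "horizon",
                    .(mind = min(night_date)), by = participant_id]
  last <- plan$nights[partition != "naive",
                      .(last = max(night_date)), by = participant_id]
  j <- merge(hz, last, by = "participant_id")
  expect_true(all(j$mind > j$last - 30))
  ## reproducible from the seed
  expect_equal(split_multilevel(n, seed = 4)$naive_participants,
               plan$naive_participants)
})

test_that("participants too short for a horizon tail go wholly to training", {
  n <- fake_nights(10, 10, nights = 20, signal = NULL)
  plan <- split_multilevel(n, seed = 2)
  expect_equal(nrow(plan$nights[partition == "horizon"]), 0L)
  expect_true(all(unique(n$participant_id) %in%
                    c(plan$naive_participants, plan$short_participants)))
})

test_that("temporal subsampling covers all timeline blocks each pass", {
  sel <- drisleep:::temporal_subsample(300, blocks = 10, passes = 1, start = 0)
  block_of <- cut(sel, breaks = floor(seq(0, 300, length.out = 11)),
                  labels = FALSE)
  expect_setequal(unique(block_of), 1:10)
  ## more passes pick more nights, never duplicates
  s3 <- drisleep:::temporal_subsample(300, blocks = 10, passes = 3, start = 0)
  expect_gt(length(s3), length(sel))
  expect_equal(anyDuplicated(s3), 0L)
  ## short timelines are taken whole
  expect_equal(drisleep:::temporal_subsample(25, passes = 3), 1:25)
})

test_that("each iteration balances classes and varies its bootstrap", {
  n <- fake_nights(8, 16, nights = 60)
  members <- lapply(1:20, function(i) fit_iteration(n, 1000 + i, nrounds = 20))
  ## under-sampling leaves equal class counts (even training size)
  expect_true(all(vapply(members, `[[`, numeric(1), "n_train") %% 2 == 0))
  ## different seeds draw different participant bootstraps
  boots <- vapply(members, function(m) paste(m$participants, collapse = ","),
                  character(1))
  expect_gt(length(unique(boots)), 1L)
})

test_that("merging averages member scores and is order-invariant", {
  n <- fake_nights(6, 6, nights = 30, seed = 3)
  members <- lapply(1:3, function(i) fit_iteration(n, 50 + i, nrounds = 30))
  ens <- merge_ensemble(members)
  x <- n[1:10]
  s <- predict(ens, x)
  hand <- rowMeans(vapply(members, function(m) {
    predict(m$model, as.matrix(x[, drisleep:::DRI_FEATURES, with = FALSE]))
  }, numeric(10)))
  expect_equal(s, hand, tolerance = 1e-12)
  expect_equal(predict(merge_ensemble(rev(members)), x), s)
  ## single member: ensemble is the member
  e1 <- merge_ensemble(members[1])
  expect_equal(predict(e1, x),
               predict(members[[1]]$model,
                       as.matrix(x[, drisleep:::DRI_FEATURES, with = FALSE])),
               tolerance = 1e-12)
  ## adding a constant-0.5 member shrinks every score toward 0.5
  e2 <- merge_ensemble(c(members, list(constant_member(0.5))))
  s2 <- predict(e2, x)
  expect_true(all(abs(s2 - 0.5) <= abs(s - 0.5) + 1e-12))
  expect_error(merge_ensemble(list()), "at least one")
})

test_that("evaluation metrics are internally consistent and bounded", {
  n <- fake_nights(8, 8, nights = 40, shift = 12, seed = 5)  # wide margin
  ens <- train_dri_si(n, n_members = 5, seed = 9, n_dummy = 2, nrounds = 60)
  ev <- evaluate_index(ens, n)
  expect_equal(ev$metrics$auc, 1)
  expect_equal(ev$metrics$mcc, 1)
  ## F1 = 2PR/(P+R) recomputed from reported precision and recall
  m <- ev$metrics
  expect_equal(m$f1, 2 * m$precision_pos * m$sensitivity /
                 (m$precision_pos + m$sensitivity), tolerance = 1e-12)
  expect_lt(abs(ev$dummy_metrics$auc - 0.5), 0.35)
  expect_true(ev$metrics$mcc >= -1 && ev$metrics$mcc <= 1)
  ## single-class input: AUC missing with a diagnostic
  expect_message(ev1 <- evaluate_index(ens, n[label == 1]), "single-class")
  expect_true(is.na(ev1$metrics$auc))
})

test_that("permutation importance is reproducible and finds the planted signal", {
  n <- fake_nights(8, 12, nights = 50, signal = "EXITS", shift = 1.5,
                   seed = 6)
  plan <- split_multilevel(n, seed = 3)
  ens <- train_dri_si(plan$nights[partition == "train"], n_members = 8,
                      seed = 11, n_dummy = 0, nrounds = 80)
  held <- plan$nights[partition != "train"]
  imp <- permutation_importance(ens, held, n_repeats = 5, seed = 2)
  expect_equal(imp$feature[1], "EXITS")
  expect_identical(permutation_importance(ens, held, n_repeats = 5, seed = 2),
                   imp)
})

test_that("score categories use half-open sextiles with a closed top bin", {
  expect_equal(categorize_scores(c(0.05, 0.99)), c(1L, 6L))
  expect_equal(categorize_scores(1 / 6), 2L)
  expect_equal(categorize_scores(c(0, 1)), c(1L, 6L))
  s <- sort(runif(200))
  expect_true(all(diff(categorize_scores(s)) >= 0))
  expect_error(categorize_scores(1.2), "\\[0, 1\\]")
  expect_error(categorize_scores(-0.1), "\\[0, 1\\]")
})
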