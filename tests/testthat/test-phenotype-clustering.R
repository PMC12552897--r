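grid_row <- function(occ, date = "2021-06-01") {
  data.table(participant_id = "p1", night_date = as.Date(date),
             window_start = as.POSIXct(paste(date, "12:00:00"), tz = "UTC"),
             len = length(occ), occupied = list(as.integer(occ)))
}

test_that("15-minute aggregation counts occupied minutes per bin", {
  full <- aggregate_15min(grid_row(rep(1L, 1440)))
  expect_equal(dim(full$bins), c(1L, 96L))
  expect_true(all(full$bins == 15))
  expect_true(all(full$mask == 0))

  empty <- aggregate_15min(rbind(grid_row(rep(1L, 1440)),
                                 grid_row(integer(1440), "2021-06-02")))
  expect_true(all(empty$bins[2, ] == 0))
  expect_true(all(empty$mask[2, ] == 1))

  ## occupancy 22:00-22:07 only: minutes 601..608 fall in bin 41
  occ <- integer(1440); occ[601:608] <- 1L
  a <- aggregate_15min(grid_row(occ))
  expect_equal(a$bins[1, 41], 8)
  expect_equal(sum(a$bins), 8)
  ## mask is the non-occupancy indicator
  expect_equal(a$mask[1, ], as.integer(a$bins[1, ] == 0), ignore_attr = TRUE)

  ## nonstandard (daylight-saving) windows are excluded with a diagnostic
  dst <- rbind(grid_row(rep(1L, 1440)),
               data.table(participant_id = "p1",
                          night_date = as.Date("2021-03-27"),
                          window_start = as.POSIXct("2021-03-27 12:00:00",
                                                    tz = "Europe/London"),
                          len = 1380L, occupied = list(rep(1L, 1380))))
  ag <- aggregate_15min(dst)
  expect_equal(nrow(ag$bins), 1L)
  expect_equal(attr(ag, "excluded")$len, 1380L)
})

test_that("the combined night dissimilarity matches hand-computed cases", {
  ## Jaccard on masks {1,2} vs {2,3}: 1 - 1/3
  x <- rep(15L, 96); x[c(1, 2)] <- 0L
  y <- rep(15L, 96); y[c(2, 3)] <- 0L
  expect_equal(drisleep:::jaccard_mask(x == 0, y == 0), 1 - 1 / 3,
               tolerance = 1e-12)
  ## identical nights -> 0
  expect_equal(night_distance(x, x), 0)
  ## complementary all-in vs all-out nights are maximal after normalization
  allin <- rep(15L, 96); allout <- rep(0L, 96)
  agg <- list(keys = NULL, bins = rbind(allin, allout, x, y),
              mask = rbind(allin == 0, allout == 0, x == 0, y == 0) + 0L)
  class(agg) <- "night_aggregates"
  dm <- night_distance_matrix(agg)
  C <- as.matrix(dm$combined)
  expect_equal(C[1, 2], 1)
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(C, t(C))
})

test_that("planted phenotypes are recovered with the correct K", {
  spec <- three_phenotype_spec(5, 20, seed = 5)   # 300 nights
  co <- generate_cohort(spec)
  agg <- aggregate_15min(resample_occupancy(co$minutes))
  cl <- cluster_nights(agg)
  truth <- co$participants[match(agg$keys$participant_id, participant_id),
                           group]
  expect_equal(cl$k, 3L)
  expect_gte(ari(cl$labels, truth), 0.9)
  ## order invariance: shuffling the nights permutes labels consistently
  perm <- sample(nrow(agg$bins))
  agg2 <- agg
  agg2$bins <- agg$bins[perm, ]; agg2$mask <- agg$mask[perm, ]
  agg2$keys <- agg$keys[perm]
  cl2 <- cluster_nights(agg2)
  expect_equal(ari(cl2$labels, cl$labels[perm]), 1)
  ## duplicated nights land in the same cluster
  agg3 <- agg
  agg3$bins <- rbind(agg$bins, agg$bins[1:20, ])
  agg3$mask <- rbind(agg$mask, agg$mask[1:20, ])
  agg3$keys <- rbind(agg$keys, agg$keys[1:20])
  cl3 <- cluster_nights(agg3)
  expect_equal(cl3$labels[301:320], cl3$labels[1:20])
})

test_that("degenerate all-identical input is rejected", {
  agg <- list(keys = NULL,
              bins = matrix(rep(15L, 96 * 12), nrow = 12, byrow = TRUE),
              mask = matrix(0L, 12, 96))
  class(agg) <- "night_aggregates"
  expect_error(cluster_nights(agg, k_range = 2:4), "degenerate")
})

test_that("relabelling orders clusters by occupancy duration deterministically", {
  bins <- rbind(matrix(rep(c(rep(10L, 70), rep(0L, 26)), 5), 5, byrow = TRUE),
                matrix(rep(c(rep(10L, 50), rep(0L, 46)), 5), 5, byrow = TRUE))
  agg <- list(keys = NULL, bins = bins, mask = (bins == 0) + 0L)
  class(agg) <- "night_aggregates"
  cl <- list(labels = rep(c(2L, 1L), each = 5), k = 2L)
  out <- relabel_by_duration(cl, agg)
  expect_equal(out$labels, rep(c(1L, 2L), each = 5))
  expect_equal(out$cluster_minutes, c(700, 500))
  ## idempotence
  expect_equal(relabel_by_duration(out, agg)$labels, out$labels)
  ## equal means: larger cluster first, then original label
  cl2 <- list(labels = c(1L, 2L, 2L), k = 2L)
  agg2 <- list(keys = NULL, bins = bins[c(1, 1, 1), ],
               mask = (bins[c(1, 1, 1), ] == 0) + 0L)
  class(agg2) <- "night_aggregates"
  out2 <- relabel_by_duration(cl2, agg2)
  expect_equal(out2$labels, c(2L, 1L, 1L))
})

test_that("LOGO classifier structure: one fold per participant, resubstitution >= CV", {
  spec <- three_phenotype_spec(4, 15, seed = 6)
  co <- generate_cohort(spec)
  agg <- aggregate_15min(resample_occupancy(co$minutes))
  cl <- cluster_nights(agg)
  nm <- night_metrics(co$minutes)
  lab <- cl$labels[match(paste(nm$participant_id, nm$night_date),
                         paste(agg$keys$participant_id, agg$keys$night_date))]
  ok <- !is.na(lab)
  sc <- train_state_classifier(nm[ok], lab[ok], nm$participant_id[ok])
  expect_equal(nrow(sc$cv) + length(sc$skipped_folds),
               length(unique(nm$participant_id[ok])))
  pred <- assign_states(sc, nm[ok])
  expect_gte(mean(pred == lab[ok]), sc$macro$accuracy)
  ## a night identical to a training night gets its training label
  expect_equal(assign_states(sc, nm[ok][7]), pred[7], ignore_attr = TRUE)
  ## class probabilities sum to one
  pr <- attr(pred, "probabilities")
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
  ## missing features are skipped with a diagnostic
  broken <- copy(nm[ok][1:3])[2, IBT := NA_real_]
  expect_message(p3 <- assign_states(sc, broken), "skipped")
  expect_true(is.na(p3[2]) && !is.na(p3[1]))
})

test_that("phenotype prevalence shifts are detectable by chi-squared", {
  ## train on the three-regime cohort, then label two cohorts with planted
  ## prevalence differences and test the label table
  spec <- three_phenotype_spec(5, 20, seed = 7)
  co <- generate_cohort(spec)
  agg <- aggregate_15min(resample_occupancy(co$minutes))
  cl <- cluster_nights(agg)
  nm <- night_metrics(co$minutes)
  lab <- cl$labels[match(paste(nm$participant_id, nm$night_date),
                         paste(agg$keys$participant_id, agg$keys$night_date))]
  ok <- !is.na(lab)
  sc <- train_state_classifier(nm[ok], lab[ok], nm$participant_id[ok])
  mk <- function(tb, ar, ex, lab2, seed2) {
    simulate_night_metrics(cohort_spec(list(cohort_group(lab2, 8, 40,
      night_profile(to_bed_mean = tb, arise_mean = ar, to_bed_sd = 0.6,
                    arise_sd = 0.6, exit_rate = ex, nap_prob = 0))),
      seed = seed2), filter = FALSE)$nights
  }
  a <- mk("19:45", "08:00", 7, "earlyish", 31)
  b <- mk("23:30", "06:40", 1, "normish", 32)
  la <- assign_states(sc, a); lb <- assign_states(sc, b)
  tab <- rbind(table(factor(la, 1:3)), table(factor(lb, 1:3)))
  expect_lt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})
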