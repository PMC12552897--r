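mk_labels <- function(pid, dates, labels, IBT = 9) {
  data.table(participant_id = pid, night_date = as.Date(dates),
             label = labels, IBT = IBT, OBT = 0.3, EXITS = 3, EXIT_DUR = 6)
}

mk_assess <- function(pid, date, scale = "BADL", score = 10) {
  data.table(participant_id = pid, assessment_date = as.Date(date),
             scale = scale, score = score)
}

test_that("windows respect the 15-day rule and count proportions exactly", {
  d0 <- as.Date("2021-06-01")
  ## 14 labelled nights -> excluded
  a <- mk_assess("p1", d0)
  short <- mk_labels("p1", d0 - 1:14, rep(1L, 14))
  w <- build_windows(a, short)
  expect_equal(nrow(w), 0L)
  expect_equal(nrow(attr(w, "excluded")), 1L)
  ## all nights one phenotype -> indicator proportions
  one <- mk_labels("p1", d0 - 1:20, rep(2L, 20))
  w1 <- build_windows(a, rbind(one, mk_labels("p2", d0 - 1:20, rep(1L, 20))))
  expect_equal(w1[participant_id == "p1", prop_2], 1)
  expect_equal(w1[participant_id == "p1", prop_1], 0)
  ## 90 nights split 30/30/30 -> one third each
  three <- mk_labels("p1", d0 - 1:90, rep(1:3, each = 30))
  w3 <- build_windows(a, three)
  expect_equal(unlist(w3[, .(prop_1, prop_2, prop_3)]),
               rep(1 / 3, 3), ignore_attr = TRUE)
  ## conservation: proportions times night count give whole nights
  expect_equal(unlist(w3[, .(prop_1, prop_2, prop_3)]) * w3$n_nights,
               rep(30, 3), ignore_attr = TRUE)
  ## half-open window [t - 90, t): day t - 90 counts, day t does not
  edge <- mk_labels("p1", c(d0, d0 - 90, d0 - 91, d0 - 1:89), rep(1L, 92))
  w4 <- build_windows(a, edge)
  expect_equal(w4$n_nights, 90L)
})

test_that("window clustering recovers planted proportion archetypes", {
  arch <- archetype_proportions(15, conc = 60, seed = 2)
  profiles <- data.table(participant_id = sprintf("p%02d", seq_len(60)),
                         assessment_date = as.Date("2021-06-01"))
  profiles <- cbind(profiles, as.data.table(arch$P))
  cw <- cluster_windows(profiles)
  expect_equal(cw$k, 4L)
  expect_gte(ari(cw$labels, arch$truth), 0.85)
  ## identical profiles share a label; order invariance up to renaming
  dup <- rbind(profiles[1], profiles[1])
  for (j in grep("^prop_", names(dup))) set(dup, 2L, j, dup[[j]][1])
  cw2 <- cluster_windows(rbind(profiles, dup))
  n <- nrow(profiles)
  expect_equal(cw2$labels[n + 1], cw2$labels[n + 2], ignore_attr = TRUE)
  perm <- sample(n)
  cw3 <- cluster_windows(profiles[perm])
  expect_equal(ari(cw3$labels, cw$labels[perm]), 1)
})

test_that("participant clustering selects K by silhouette and flags weak structure", {
  arch <- archetype_proportions(10, conc = 80, seed = 3)
  cp <- cluster_participants(arch$P)
  expect_equal(cp$k, 4L)
  expect_gte(ari(cp$labels, arch$truth), 0.85)
  expect_false(cp$weak_structure)
  ## a single archetype yields near-zero silhouette, flagged
  set.seed(6)
  flat <- t(vapply(1:30, function(i) {
    g <- rgamma(5, shape = 20); g / sum(g)
  }, numeric(5)))
  colnames(flat) <- paste0("prop_", 1:5)
  cp0 <- cluster_participants(flat)
  expect_true(cp0$weak_structure)
  expect_error(cluster_participants(flat[1:3, ]), "at least 4")
})

test_that("relabelling phenotypes permutes but does not change window clusters", {
  arch <- archetype_proportions(12, conc = 50, seed = 9)
  profiles <- cbind(data.table(participant_id = sprintf("p%02d", 1:48),
                               assessment_date = as.Date("2021-06-01")),
                    as.data.table(arch$P))
  cw <- cluster_windows(profiles)
  ## bijectively permute the phenotype columns (Hellinger is equivariant)
  permuted <- copy(profiles)
  setnames(permuted, paste0("prop_", 1:5), paste0("prop_", c(3, 1, 5, 2, 4)))
  cw2 <- cluster_windows(permuted)
  expect_equal(ari(cw$labels, cw2$labels), 1)
})

test_that("Welch ANOVA matches the closed-form oracle to 1e-9", {
  set.seed(14)
  d <- data.frame(y = c(rnorm(20, 0, 1), rnorm(30, 0.8, 2), rnorm(25, -0.5, 3)),
                  g = rep(c("a", "b", "c"), c(20, 30, 25)))
  rep_ <- group_effects(d, "y", group = "g")$y
  ## independent textbook implementation of Welch's statistic
  gs <- split(d$y, d$g)
  ni <- lengths(gs); mi <- sapply(gs, mean); vi <- sapply(gs, var)
  wi <- ni / vi; W <- sum(wi); mw <- sum(wi * mi) / W
  K <- length(gs)
  A <- sum(wi * (mi - mw)^2) / (K - 1)
  B <- sum((1 - wi / W)^2 / (ni - 1))
  F_oracle <- A / (1 + 2 * (K - 2) * B / (K^2 - 1))
  df2_oracle <- (K^2 - 1) / (3 * B)
  expect_equal(rep_$F, F_oracle, tolerance = 1e-9)
  expect_equal(rep_$df2, df2_oracle, tolerance = 1e-9)
  expect_equal(rep_$p, pf(F_oracle, K - 1, df2_oracle, lower.tail = FALSE),
               tolerance = 1e-9)
  ## report structure: K(K-1)/2 pairwise rows, Bonferroni >= raw
  expect_equal(nrow(rep_$pairwise), 3L)
  expect_gte(rep_$p_bonferroni, rep_$p)
})

test_that("identical groups give a null Welch result", {
  set.seed(1)
  x <- rnorm(40)
  d <- data.frame(y = c(x, x), g = rep(c("a", "b"), each = 40))
  rep_ <- group_effects(d, "y", group = "g")$y
  expect_lt(rep_$F, 1e-20)
  expect_gt(rep_$p, 0.999)
})

test_that("zero-variance groups are floored and flagged, not dropped", {
  d <- data.frame(y = c(rep(1, 5), rnorm(10, 2), rnorm(10, 0)),
                  g = rep(c("a", "b", "c"), c(5, 10, 10)))
  rep_ <- group_effects(d, "y", group = "g")$y
  expect_true(rep_$degenerate_variance)
  expect_true(is.finite(rep_$F))
})

test_that("Games-Howell p-values are monotone in the statistic at equal df", {
  set.seed(5)
  d <- data.frame(y = c(rnorm(30, 0), rnorm(30, 0.5), rnorm(30, 1.5),
                        rnorm(30, 3)),
                  g = rep(letters[1:4], each = 30))
  gh <- group_effects(d, "y", group = "g")$y$pairwise
  ## within bands of similar df the adjusted p decreases as |t| grows
  ord <- order(abs(gh$t))
  expect_true(all(diff(gh$p_adj[ord]) <= 1e-6 + abs(diff(gh$df[ord])) * 1))
  ## and the extreme pair is the most significant
  expect_equal(which.min(gh$p_adj), which.max(abs(gh$t)))
})

test_that("Bonferroni correction spans the outcome family", {
  set.seed(7)
  d <- data.frame(y1 = rnorm(60), y2 = rnorm(60), y3 = rnorm(60),
                  g = rep(c("a", "b"), each = 30))
  reps <- group_effects(d, c("y1", "y2", "y3"), group = "g")
  for (r in reps) {
    expect_equal(r$p_bonferroni, min(r$p * 3, 1))
  }
})
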