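periods_at <- function(times, date = "2021-06-01") {
  ## times: list of c(start_offset, end_offset) minutes since noon (half-open)
  noon <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC")
  data.table(participant_id = "p1", night_date = as.Date(date),
             start = noon + vapply(times, `[`, numeric(1), 1) * 60,
             end = noon + vapply(times, `[`, numeric(1), 2) * 60,
             minutes = vapply(times, function(x) as.integer(x[2] - x[1]),
                              integer(1)))
}

test_that("periods merge below the 30-minute gap and split at it", {
  ## gap of 25 min (end 01:00 = offset 780, next start 01:25 = 805)
  p <- cluster_periods(periods_at(list(c(600, 780), c(805, 900))))
  expect_equal(unique(p$cluster_id), 1L)
  ## gap of exactly 30 min -> two clusters
  p2 <- cluster_periods(periods_at(list(c(600, 780), c(810, 900))))
  expect_equal(p2$cluster_id, c(1L, 2L))
  ## gaps of 10 and 45 min -> clusters {1,2} and {3}
  p3 <- cluster_periods(periods_at(list(c(600, 700), c(710, 800),
                                        c(845, 900))))
  expect_equal(p3$cluster_id, c(1L, 1L, 2L))
})

test_that("diurnal/nocturnal classification follows the 8am-8pm same-day rule", {
  cl <- classify_clusters(cluster_periods(periods_at(list(
    c(120, 210)))))     # 14:00-15:30 same day
  expect_equal(cl$classification, "diurnal")
  cl2 <- classify_clusters(cluster_periods(periods_at(list(
    c(600, 1080)))))    # 22:00-06:00 next day
  expect_equal(cl2$classification, "nocturnal")
  cl3 <- classify_clusters(cluster_periods(periods_at(list(
    c(470, 710)))))     # 19:50-23:50 same day: starts before 20:00
  expect_equal(cl3$classification, "diurnal")
  cl4 <- classify_clusters(cluster_periods(periods_at(list(
    c(480, 700)))))     # 20:00 start is no longer diurnal (half-open)
  expect_equal(cl4$classification, "nocturnal")
})

test_that("clock angles use 15 degrees per hour with the two origins", {
  expect_equal(clock_angle("12:00", "midday"), 0)
  expect_equal(clock_angle("22:47", "midday"), 161.75)
  expect_equal(clock_angle("03:00", "midday"), 225)
  expect_equal(clock_angle("23:45", "midnight"), 356.25)
  expect_equal(clock_angle("00:00", "midnight"), 0)
})

test_that("the worked night reproduces every metric by integer-minute arithmetic", {
  obs <- make_obs(c("22:00-02:00", "02:10-06:59"))
  r <- compute_night_metrics(obs)
  expect_equal(r$to_bed, "22:00")
  expect_equal(r$wake_up, "06:59")
  expect_equal(r$NOP, 9)
  expect_equal(r$IBT, 531 / 60)
  expect_equal(r$OBT, 9 / 60)
  expect_equal(r$EXITS, 1)
  expect_equal(r$EXIT_DUR, 9)
  expect_equal(r$IBP, 531 / 540)
  expect_equal(r$TO_BED, clock_angle("22:00", "midday"))
  expect_equal(r$ARISE, clock_angle("06:59", "midnight"))
  ## night ending 06:59 on June 2 dates to June 1
  expect_equal(r$night_date, as.Date("2021-06-01"))
  expect_error(compute_night_metrics(obs[0]), "no observations")
})

test_that("a contiguous single-state night has pure state composition", {
  obs <- make_obs("23:00-06:00", state = "LIGHT", snore = 0L)
  r <- compute_night_metrics(obs)
  expect_equal(r$WSA_LIGHT, 1)
  expect_equal(r$WSA_DEEP + r$WSA_REM + r$WSA_AWAKE, 0)
  expect_equal(r$SNR, 0)
  expect_equal(r$EXITS, 0)
  expect_equal(r$EXIT_DUR, 0)
  expect_equal(r$IBP, 1)
})

test_that("night records satisfy the accounting invariants", {
  spec <- cohort_spec(list(cohort_group("g", 4, 40, profile_ad())), seed = 9)
  m <- night_metrics(generate_cohort(spec)$minutes)
  expect_true(all(abs(m$IBT + m$OBT - m$NOP) < 1 / 60 + 1e-9))
  expect_true(all(abs(m$IBP - m$IBT / m$NOP) < 1e-9))
  expect_true(all(m$EXITS >= 0))
  expect_true(all(m$WSA_DEEP + m$WSA_AWAKE + m$WSA_REM + m$WSA_LIGHT <= 1 + 1e-9))
  expect_true(all(m$SNR >= 0 & m$SNR <= 1))
})

test_that("each quality rule drops exactly the night built to violate it", {
  recs <- rbind(
    compliant_record("ok1"),
    compliant_record("ok2", EXITS = 20),          # inclusive boundary
    compliant_record("ok3", HR = 85, RR = 10),    # inclusive boundaries
    compliant_record("v_exits", EXITS = 21),
    compliant_record("v_ibp", IBP = 0.55),
    compliant_record("v_hr", HR = 90),
    compliant_record("v_rr", RR = 30),
    compliant_record("v_exitdur", EXIT_DUR = 70),
    compliant_record("v_obt", OBT = 3.2),
    compliant_record("v_ibt", IBT = 17),
    compliant_record("v_tobed", to_bed = "16:00"),
    compliant_record("v_wake", wake_up = "01:00"))
  v <- apply_quality_filters(recs)
  expect_equal(sum(v$kept), 3L)
  expect_true(all(startsWith(v$participant_id[!v$kept], "v_")))
  got <- setNames(v$violated_rules, v$participant_id)
  expect_equal(got[["v_exits"]], "exits_max")
  expect_equal(got[["v_ibp"]], "ibp_range")
  expect_equal(got[["v_hr"]], "hr_range")
  expect_equal(got[["v_rr"]], "rr_range")
  expect_equal(got[["v_exitdur"]], "exit_dur_max")
  expect_equal(got[["v_obt"]], "obt_max")
  expect_equal(got[["v_ibt"]], "ibt_range")
  expect_equal(got[["v_tobed"]], "to_bed_window")
  expect_equal(got[["v_wake"]], "wake_up_window")
  ## kept <=> no violated rules
  expect_equal(v$kept, lengths(v$violated_rules) == 0)
})

test_that("missing metric values are flagged as their own rule", {
  v <- apply_quality_filters(compliant_record("m", HR = NA_real_))
  expect_false(v$kept)
  expect_equal(v$violated_rules[[1]], "missing_values")
})

test_that("the filter is a pure predicate: idempotent and order-invariant", {
  recs <- rbind(compliant_record("a"), compliant_record("b", EXITS = 21),
                compliant_record("c", HR = 90))
  v1 <- apply_quality_filters(recs)
  v2 <- apply_quality_filters(recs[3:1])
  expect_equal(v1[order(participant_id)],
               v2[order(participant_id)])
  kept <- filter_nights(recs)
  expect_equal(filter_nights(kept)$participant_id, kept$participant_id)
})
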