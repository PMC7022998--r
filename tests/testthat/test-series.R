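make_series <- function() {
  start <- as.Date("2023-10-02")  # a Monday
  sessions <- data.frame(
    date = c(start + 0:2, start + 7, start + 9),
    sport = "swimming",
    rpe = c(6, 7, 5, 8, 4),
    duration_min = c(60, 90, 60, 120, 45),
    distance_m = c(4000, 5000, 3500, 6000, 2000)
  )
  wellbeing <- data.frame(
    date = c(start + 1, start + 4, start + 8),
    sleep_quality = 5L, sleep_quantity = 5L, soreness = 4L,
    enjoyment = 6L, stress = 3L, global_recovery = c(5L, 6L, 3L)
  )
  poms <- data.frame(
    date = start + 13, anger = 2, confusion = 3, depression = 1,
    fatigue = 4, tension = 2, vigour = 10
  )
  performances <- data.frame(
    date = c(start + 5, start + 6, start + 12),
    discipline = "100 free",
    time_s = c(61.0, 59.5, 60.5), previous_pb_s = 60.0
  )
  athlete_series("A1", sessions, wellbeing, poms, performances,
                 start_date = start, n_weeks = 4)
}

test_that("weekly aggregation yields one record per study week", {
  m <- weekly_aggregate(make_series())
  expect_equal(nrow(m), 4)
  expect_equal(m$week, 1:4)
  # week 1 means over its three sessions
  expect_equal(m$mean_distance[1], mean(c(4000, 5000, 3500)))
  expect_equal(m$total_load[1], 6 * 60 + 7 * 90 + 5 * 60)
  # empty weeks have zero load and undefined monotony/strain
  expect_equal(m$total_load[3], 0)
  expect_true(is.na(m$monotony[3]))
  expect_true(is.na(m$strain[3]))
  # monotony from the 7 daily totals of week 1 (incl. rest days)
  daily <- c(360, 630, 300, 0, 0, 0, 0)
  expect_equal(m$monotony[1], mean(daily) / sd(daily))
  expect_equal(m$strain[1], m$total_load[1] * m$monotony[1])
})

test_that("best weekly %PBT is the maximum and missing without competition", {
  m <- weekly_aggregate(make_series())
  expect_equal(m$best_pbt[1], max(percent_pbt(60, c(61.0, 59.5))))
  expect_equal(m$best_pbt[2], percent_pbt(60, 60.5))
  expect_true(is.na(m$best_pbt[3]))
})

test_that("wellness and mood aggregate to weekly means, NA when absent", {
  m <- weekly_aggregate(make_series())
  expect_equal(m$mean_recovery[1], mean(c(5, 6)))
  expect_equal(m$mean_recovery[2], 3)
  expect_true(is.na(m$mean_recovery[3]))
  expect_equal(m$tmd[2], (2 + 3 + 1 + 4 + 2) - 10)
  expect_true(is.na(m$tmd[1]))
})

test_that("a 26-week synthetic season aggregates to exactly 26 records", {
  a <- simulate_athlete(cohort_config(seed = 3), 1)
  expect_equal(nrow(weekly_aggregate(a)), 26)
})

test_that("combinations pick the documented axes and normalize to [0,1]", {
  a <- simulate_athlete(cohort_config(seed = 3), 1)
  m <- weekly_aggregate(a)
  tr1 <- build_combination(m, 1)
  expect_equal(tr1$x, normalize_series(m$mean_distance[tr1$week]))
  expect_equal(tr1$y, normalize_series(m$mean_session_rpe[tr1$week]))
  for (cb in 1:4) {
    tr <- suppressWarnings(build_combination(m, cb))
    expect_true(all(tr$x >= 0 & tr$x <= 1))
    expect_true(all(tr$y >= 0 & tr$y <= 1))
    expect_equal(max(tr$x), 1)
    expect_equal(max(tr$y), 1)
  }
  expect_error(build_combination(m, 9), "unknown combination")
})

test_that("combination 5 drops the ACWR-undefined opening weeks", {
  a <- simulate_athlete(cohort_config(seed = 3), 1)
  m <- weekly_aggregate(a)
  expect_warning(tr5 <- build_combination(m, 5), "dropped")
  expect_false(any(tr5$week %in% 1:3))
})

test_that("labels in triplets exist exactly for competition weeks", {
  m <- weekly_aggregate(make_series())
  tr <- build_combination(m, 1)
  expect_equal(is.na(tr$label), is.na(tr$z_pct))
  expect_equal(tr$label[tr$week == 1], 1L)   # 59.5 s beat the 60 s PB
  expect_equal(tr$label[tr$week == 2], -1L)  # 60.5 s did not
})

test_that("series validation rejects out-of-range records", {
  s <- make_series()
  bad <- s$sessions; bad$rpe[2] <- 12
  expect_error(athlete_series("A", bad, start_date = s$start_date,
                              n_weeks = 4), "row 2.*rpe|rpe")
  late <- s$sessions; late$date[1] <- as.Date("2024-06-01")
  expect_error(athlete_series("A", late, start_date = s$start_date,
                              n_weeks = 4), "window")
})

test_that("inclusion prerequisites apply the documented strict cuts", {
  s <- make_series()
  ok <- apply_prerequisites(s, attendance = 0.8,
                            response_rates = c(0.9, 0.85))
  expect_true(ok$include)
  expect_length(ok$reasons, 0)

  # response rate exactly at the 80% boundary fails (strict inequality)
  r <- apply_prerequisites(s, attendance = 0.8,
                           response_rates = c(0.80, 0.9))
  expect_false(r$include)
  expect_match(r$reasons, "response rate", all = FALSE)

  # attendance at exactly 75% fails
  r <- apply_prerequisites(s, attendance = 0.75, response_rates = 0.9)
  expect_false(r$include)

  # a season improving in every competition is excluded
  fast <- s
  fast$performances$time_s <- c(58, 57.5, 59)
  fast <- athlete_series("A", fast$sessions, fast$wellbeing, fast$poms,
                         fast$performances, start_date = fast$start_date,
                         n_weeks = 4)
  r <- apply_prerequisites(fast, 0.9, c(0.9, 0.9))
  expect_false(r$include)
  expect_match(r$reasons, "under 100", all = FALSE)
})
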