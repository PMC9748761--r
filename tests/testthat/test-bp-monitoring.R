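test_that("measurement schedules carry the protocol slot counts", {
  opt <- generate_schedule("optimal", "2022-01-03")
  expect_equal(nrow(opt), 28)
  expect_equal(length(unique(opt$date)), 7)
  expect_equal(range(opt$date), as.Date(c("2022-01-03", "2022-01-09")))
  minimal <- generate_schedule("minimal", "2022-01-03")
  expect_equal(nrow(minimal), 12)
  expect_equal(length(unique(minimal$date)), 3)
  # 2 sessions x 2 replicates on every scheduled date, both windows
  expect_true(all(table(opt$date) == 4))
  expect_true(all(table(minimal$date) == 4))
})

test_that("constant weekly series: exact means, no exclusions, optimal", {
  s <- weekly_average(week_stream(120, 70), as.Date("2022-01-03"))
  expect_equal(s$mean_sbp, 120)
  expect_equal(s$mean_dbp, 70)
  expect_equal(s$n_excluded_sbp, 0)
  expect_equal(s$n_excluded_dbp, 0)
  expect_equal(s$sufficiency, "optimal")
})

test_that("a 3-SD outlier is excluded per channel and the mean recovers", {
  sbp <- c(rep(120, 27), 250)
  bp <- week_stream(sbp, 70)
  # oracle: direct mean/SD computation on the raw 28-value vector
  z_outlier <- abs(250 - mean(sbp)) / sd(sbp)
  expect_gt(z_outlier, 3)
  s <- weekly_average(bp, as.Date("2022-01-03"))
  expect_equal(s$n_excluded_sbp, 1)
  expect_equal(s$mean_sbp, 120) # mean of survivors
  # the paired DBP value survives: per-channel, not per-reading, exclusion
  expect_equal(s$n_excluded_dbp, 0)
  expect_equal(s$mean_dbp, 70)
})

test_that("sufficiency grading follows the readings-and-days rules", {
  # 11 readings over 3 days: below the minimal count
  dates <- rep(as.Date("2022-01-03") + 0:2, times = c(4, 4, 3))
  bp <- bp_stream(paste(dates, "08:00:00"), 140, 85)
  expect_equal(weekly_average(bp, "2022-01-03")$sufficiency, "insufficient")
  # 12 over 3 days: minimal
  bp12 <- bp_stream(paste(rep(as.Date("2022-01-03") + 0:2, each = 4),
                          "08:00:00"), 140, 85)
  expect_equal(weekly_average(bp12, "2022-01-03")$sufficiency, "minimal")
  # 28 readings crammed into 6 days: not optimal (needs 7 distinct days)
  bp28 <- bp_stream(paste(rep(as.Date("2022-01-03") + 0:5, length.out = 28),
                          "08:00:00"), 140, 85)
  expect_equal(weekly_average(bp28, "2022-01-03")$sufficiency, "minimal")
  # empty input is flagged, not an error
  empty <- weekly_average(NULL, "2022-01-03")
  expect_equal(empty$sufficiency, "insufficient")
  expect_true(is.na(empty$mean_sbp))
})

test_that("weekly average is permutation-invariant and matches a direct oracle", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(12:28, 1)
    dates <- sort(sample(as.Date("2022-01-03") + 0:6, n, replace = TRUE))
    sbp <- round(rnorm(n, 140, 12) + ifelse(runif(n) < 0.1, 60, 0))
    dbp <- pmin(round(rnorm(n, 85, 8)), sbp - 10)
    bp <- bp_stream(paste(dates, "08:00:00"), sbp, dbp)
    s1 <- weekly_average(bp, "2022-01-03")
    shuffled <- bp[sample(nrow(bp)), ]
    s2 <- weekly_average(shuffled, "2022-01-03")
    expect_equal(s2$mean_sbp, s1$mean_sbp)
    expect_equal(s2$mean_dbp, s1$mean_dbp)
    # independent oracle: single-pass filter on the raw mean/sample SD
    oracle <- function(x) mean(x[abs(x - mean(x)) <= 3 * sd(x)])
    expect_equal(s1$mean_sbp, oracle(sbp))
    expect_equal(s1$mean_dbp, oracle(dbp))
    # only genuinely extreme values are ever excluded
    expect_equal(s1$n_excluded_sbp, sum(abs(sbp - mean(sbp)) > 3 * sd(sbp)))
  }
})

test_that("readings outside the window are refused", {
  bp <- bp_stream("2022-01-11 08:00:00", 140, 85)
  expect_error(weekly_average(bp, "2022-01-03"), "outside")
})

test_that("goal classification at standard and frail goals", {
  expect_equal(week_summary(129.5, 79)$goal$status, "at_goal")
  expect_equal(week_summary(134, 84, frail = TRUE)$goal$status, "at_goal")
  expect_equal(week_summary(134, 84, frail = FALSE)$goal$status, "above_goal")
  g <- week_summary(131, 70)$goal
  expect_equal(g$status, "above_goal")
  expect_false(g$safety_floor_flag)
  expect_true(g$near_goal_within_margin) # 1 mmHg above on SBP only
  # 10 mmHg above goal is no longer "near"
  expect_false(week_summary(140, 70)$goal$near_goal_within_margin)
  # both channels above: both distances must be inside the margin
  expect_true(week_summary(135, 84)$goal$near_goal_within_margin)
  expect_false(week_summary(135, 95)$goal$near_goal_within_margin)
})

test_that("safety floor flags weekly means below 105/50", {
  expect_true(week_summary(104, 70)$goal$safety_floor_flag)
  g <- weekly_average(week_stream(120, 49), as.Date("2022-01-03"))
  expect_true(goal_status(g, FALSE)$safety_floor_flag)
  expect_false(week_summary(105, 50)$goal$safety_floor_flag)
})

test_that("goal classification refuses an insufficient week", {
  s <- weekly_average(NULL, "2022-01-03")
  expect_error(goal_status(s, FALSE), "sufficiency")
})

test_that("program-state transitions follow the weekly-report rules", {
  at_goal <- weekly_average(week_stream(120, 70), as.Date("2022-01-03"))
  above <- weekly_average(week_stream(150, 95), as.Date("2022-01-03"))
  # at goal before any medication change: white-coat diagnosis
  expect_equal(classify_transition("enrolled_baseline", at_goal,
                                   any_med_change_yet = FALSE), "white_coat")
  expect_equal(classify_transition("enrolled_baseline", above), "active_titration")
  # controlled 2 weeks after titration: maintenance
  expect_equal(classify_transition("active_titration", at_goal,
                                   weeks_since_titration = 2), "maintenance")
  expect_equal(classify_transition("active_titration", at_goal,
                                   weeks_since_titration = 1), "active_titration")
  expect_equal(classify_transition("maintenance", above), "active_titration")
  # an insufficient week never moves the state
  insuf <- weekly_average(NULL, "2022-01-03")
  expect_equal(classify_transition("active_titration", insuf), "active_titration")
})

test_that("maintenance is only ever left when above goal", {
  set.seed(13)
  for (i in 1:200) {
    sbp <- sample(100:170, 1); dbp <- sample(55:105, 1)
    dbp <- min(dbp, sbp - 15)
    frail <- runif(1) < 0.3
    s <- weekly_average(week_stream(sbp, dbp), as.Date("2022-01-03"))
    new <- classify_transition("maintenance", s, frail,
                               any_med_change_yet = TRUE,
                               weeks_since_titration = runif(1, 0, 10))
    if (new != "maintenance") {
      expect_equal(goal_status(s, frail)$status, "above_goal")
      expect_equal(new, "active_titration")
    }
  }
})
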