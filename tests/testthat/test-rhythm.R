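test_that("percent-of-max normalization and linear interpolation follow the
           stated identities", {
  x <- hour_cohort(c(6, 12, 18, 9, 15, 21),
                   c(100, 150, 200, 120, 180, 160))
  p <- to_percent_of_max(x, "TC", min_samples = 6)
  expect_s3_class(p, "daily_profile")
  expect_equal(max(p$pct[p$observed]), 100)
  # observed points are value / day-max * 100
  expect_equal(p$pct[p$minute == 6 * 60], 50)
  expect_equal(p$pct[p$minute == 18 * 60], 100)
  # no extrapolation outside first..last observed minute
  expect_equal(range(p$minute), c(6 * 60, 21 * 60))

  # midpoint interpolation on a 3-point profile
  y <- hour_cohort(c(6, 12, 18), c(100, 150, 200))
  py <- to_percent_of_max(y, "TC", min_samples = 3)
  expect_equal(py$pct[py$minute == 9 * 60], 62.5)
  expect_false(py$observed[py$minute == 9 * 60])

  # days under the sample floor are excluded, not an error
  expect_message(
    expect_null(to_percent_of_max(y, "TC", min_samples = 6)), "excluded")

  # all-equal values give a valid constant-100 profile
  z <- hour_cohort(seq(6, 16, by = 2), rep(150, 6))
  pz <- to_percent_of_max(z, "TC")
  expect_true(all(pz$pct == 100))
})

test_that("normalization is scale-invariant through the whole chain", {
  hours <- seq(6, 22, by = 2)
  vals <- c(150, 140, 155, 170, 185, 200, 190, 175, 160)
  a <- to_percent_of_max(hour_cohort(hours, vals), "TC")
  b <- to_percent_of_max(hour_cohort(hours, vals * 3.7), "TC")
  expect_equal(a$pct, b$pct)
})

test_that("aggregation takes the per-minute median across contributing
           profiles and matches a sort-based oracle", {
  hours <- seq(6, 18, by = 2)
  p1 <- to_percent_of_max(hour_cohort(hours, c(40, 50, 60, 80, 100, 90, 70),
                                      participant = "A"), "TC")
  p2 <- to_percent_of_max(hour_cohort(hours, c(60, 70, 80, 90, 100, 95, 85),
                                      participant = "B"), "TC")
  agg1 <- aggregate_profiles(list(p1))
  expect_equal(agg1$value, p1$pct)

  agg <- aggregate_profiles(list(p1, p2))
  m6 <- agg$value[agg$minute == 6 * 60]
  expect_equal(m6, mean(c(40, 60)))  # median of two = midpoint

  # 13 constant profiles at distinct levels: per-minute sort oracle
  levels <- seq(40, 100, length.out = 13)
  profs <- lapply(seq_along(levels), function(i) {
    p <- to_percent_of_max(hour_cohort(hours, rep(1, 7),
                                       participant = sprintf("C%02d", i)),
                           "TC")
    p$pct <- rep(levels[i], length(p$pct))
    p
  })
  agg13 <- aggregate_profiles(profs)
  expect_true(all(agg13$value == sort(levels)[7]))
  aggm <- aggregate_profiles(profs, stat = "mean")
  expect_true(all(abs(aggm$value - mean(levels)) < 1e-9))
})

test_that("the centered moving average matches direct summation, truncates
           at the edges, and commutes with adding a constant", {
  hours <- seq(6, 22, by = 1)
  set.seed(4)
  vals <- runif(length(hours), 50, 100)
  p <- to_percent_of_max(hour_cohort(hours, vals), "TC")
  agg <- aggregate_profiles(list(p))
  sm <- moving_average(agg, hours = 2)

  # constant in, constant out
  cp <- agg; cp$value <- rep(70, nrow(cp))
  expect_true(all(moving_average(cp, 2)$value == 70))

  # direct-summation oracle at 20 random minutes
  idx <- sample(nrow(agg), 20)
  for (i in idx) {
    m0 <- agg$minute[i]
    win <- abs(agg$minute - m0) <= 60
    expect_equal(sm$value[i], mean(agg$value[win]), tolerance = 1e-9)
  }

  # shift-equivariance under adding a constant
  shifted <- agg; shifted$value <- agg$value + 13
  expect_equal(moving_average(shifted, 2)$value, sm$value + 13,
               tolerance = 1e-9)
})

test_that("the peak/trough test matches the tied-group rank formula and
           handles degenerate ties", {
  # trough all 50 (n=20), peak all 100 (n=20): two tied groups
  mk <- function(participant, hours, vals)
    to_percent_of_max(hour_cohort(hours, vals, participant = participant),
                      "TC", min_samples = 6)
  profs <- lapply(1:10, function(i) {
    mk(sprintf("P%d", i), c(5, 5.5, 15, 15.5, 20, 21),
       c(50, 50, 100, 100, 80, 70))
  })
  wt <- peak_trough_test(profs, time_window(5, 7), time_window(15, 17))
  expect_equal(unname(wt$n), c(20L, 20L))
  # hand formula for two groups of 20 with two distinct tied values:
  # ranks 10.5 (x20) and 30.5 (x20); H with tie correction
  n <- 40; R1 <- 20 * 10.5; R2 <- 20 * 30.5
  H <- (12 / (n * (n + 1))) * (R1^2 / 20 + R2^2 / 20) - 3 * (n + 1)
  tie <- 1 - (2 * (20^3 - 20)) / (n^3 - n)
  expect_equal(unname(wt$statistic), H / tie, tolerance = 1e-9)
  expect_lt(wt$p.value, 0.001)

  # degenerate: identical constant in both windows
  flat <- lapply(1:3, function(i)
    mk(sprintf("F%d", i), c(5, 6, 10, 15, 16, 20), rep(100, 6)))
  wf <- peak_trough_test(flat, time_window(5, 7), time_window(15, 17))
  expect_true(wf$degenerate)
  expect_equal(wf$p.value, 1)

  # empty window errors name the window
  expect_error(peak_trough_test(profs, time_window(1, 2),
                                time_window(15, 17)), "trough")
})

test_that("window tests use observed samples only, never interpolated
           minutes", {
  p <- to_percent_of_max(hour_cohort(c(5, 6.5, 12, 15, 16.5, 20),
                                     c(50, 52, 80, 100, 98, 70)), "TC",
                         min_samples = 6)
  wt <- peak_trough_test(list(p, p), time_window(5, 7),
                         time_window(15, 17))
  # 2 observed per window per profile despite ~120 interpolated minutes
  expect_equal(unname(wt$n), c(4L, 4L))
})

test_that("the full pipeline recovers a planted daily rhythm and flags the
           arrhythmic channel", {
  sim <- generate_cohort(sim_config(seed = 2L))
  rep_tc <- rhythm_pipeline(sim$cohort, "TC")
  expect_equal(rep_tc$status, "ok")
  expect_equal(rep_tc$n_profiles, 13L)
  expect_true(dominant_period(rep_tc$fit) >= 23 &&
                dominant_period(rep_tc$fit) <= 25)
  expect_gte(rep_tc$fit$adj.r.squared, 0.85)
  expect_lt(abs(acrophase(rep_tc$fit) - 16), 1.5)
  expect_lt(rep_tc$window_test$p.value, 0.05)

  # HDL has no planted daily component: individual fits should not reach
  # the adjusted R^2 >= 0.5 that rhythmic channels show
  rep_hdl <- rhythm_pipeline(sim$cohort, "HDL")
  expect_true(mean(rep_hdl$individual_summary$adj.r.squared >= 0.5) <= 0.2)

  # scale invariance of the full chain: scaling raw values changes nothing
  scaled <- sim$cohort
  scaled$value <- scaled$value * 2.5
  rep_s <- rhythm_pipeline(scaled, "TC")
  expect_equal(rep_s$fit$r.squared, rep_tc$fit$r.squared, tolerance = 1e-9)
  expect_equal(rep_s$window_test$p.value, rep_tc$window_test$p.value,
               tolerance = 1e-12)
})

test_that("a cohort with no qualifying slice reports empty status and a
           constant cohort propagates the degenerate-fit flag", {
  tiny <- hour_cohort(c(6, 12), c(150, 160))
  r <- rhythm_pipeline(tiny, "TC")
  expect_equal(r$status, "empty")

  flat <- generate_cohort(quiet_config(n_participants = 3L))
  rf <- rhythm_pipeline(flat$cohort, "TC")
  expect_true(rf$fit$degenerate)
})

test_that("parameter recovery: acrophase and period errors stay small over
           repeated simulations", {
  acro_err <- period_err <- numeric(8)
  for (s in 1:8) {
    sim <- generate_cohort(sim_config(seed = 100L + s))
    fit <- rhythm_pipeline(sim$cohort, "TC")$fit
    acro_err[s] <- abs(acrophase(fit) - 16)
    period_err[s] <- abs(dominant_period(fit) - 24)
  }
  expect_lte(median(acro_err), 1)
  expect_lte(median(period_err), 1)
})
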