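# brute-force linear-scan classifier used as the independent oracle
scan_classify <- function(boundaries, labels, value) {
  vapply(value, function(v) {
    i <- 1L
    for (b in boundaries) if (v >= b) i <- i + 1L else break
    labels[i]
  }, character(1))
}

test_that("classification follows the lower-inclusive boundary convention", {
  sch <- risk_scheme()
  expect_equal(classify(sch, "TC", 195), "desirable")
  expect_equal(classify(sch, "TC", 200), "borderline-high")  # boundary up
  expect_equal(classify(sch, "TC", 240), "high")
  expect_equal(classify(sch, "HDL", c(39.9, 40, 60)),
               c("low", "intermediate", "high"))
  expect_equal(classify(sch, "TG", c(149, 150, 200, 500)),
               c("normal", "borderline-high", "high", "very-high"))
  expect_error(classify(sch, "LDL", 100), "unknown analyte")
})

test_that("classification agrees with an exhaustive boundary-scan oracle
           on a 1 mg/dL grid", {
  sch <- risk_scheme()
  grid <- seq(1, 600, by = 1)
  for (a in c("TC", "HDL", "TG"))
    expect_identical(classify(sch, a, grid),
                     scan_classify(sch$boundaries[[a]], sch$labels[[a]],
                                   grid))
  # monotone non-decreasing category index as value increases
  for (a in c("TC", "HDL", "TG")) {
    idx <- match(classify(sch, a, grid), sch$labels[[a]])
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("crossing is visiting two or more categories and is invariant to
           sample order and duplication", {
  sch <- risk_scheme()
  x <- hour_cohort(c(6, 12, 18, 24), c(180, 210, 185, 180))
  r <- crossing_report(x, sch, grouping = "within_day")
  tc <- r$participants[r$participants$analyte == "TC", ]
  expect_true(tc$crossed)
  expect_equal(tc$n_categories, 2L)
  expect_equal(tc$range, 30)

  y <- hour_cohort(c(6, 12, 18), c(180, 185, 190))
  ry <- crossing_report(y, sch, grouping = "within_day")
  expect_false(ry$participants$crossed[1])

  # shuffled + duplicated values give the same verdict
  z <- hour_cohort(c(6, 9, 12, 15, 18), c(210, 180, 180, 210, 185))
  expect_true(crossing_report(z, sch)$participants$crossed[1])
})

test_that("cohort crossing percentages match a designed noiseless cohort
           and are invariant to participant relabeling", {
  sch <- risk_scheme()
  # 20 participants; exactly 9 designed to straddle the TC 200 boundary
  cross <- c(rep(TRUE, 9), rep(FALSE, 11))
  rows <- do.call(rbind, lapply(seq_along(cross), function(i) {
    v <- if (cross[i]) c(195, 205, 198) else c(180, 190, 185)
    data.frame(participant = sprintf("S%02d", i),
               timestamp = sprintf("2024-03-01 %02d:00", c(6, 12, 18)),
               analyte = "TC", value = v, stringsAsFactors = FALSE)
  }))
  x <- as_lipid_cohort(rows)
  r <- crossing_report(x, sch, grouping = "within_day")
  tc <- r$cohort[r$cohort$analyte == "TC", ]
  expect_equal(tc$n, 20L)
  expect_equal(tc$pct_crossed, 45)  # exactly 9/20

  # relabel participants: cohort percentage unchanged
  rows2 <- rows
  rows2$participant <- sprintf("Z%02d", 21 - as.integer(
    sub("S", "", rows2$participant)))
  r2 <- crossing_report(as_lipid_cohort(rows2), sch)
  expect_equal(r2$cohort$pct_crossed, r$cohort$pct_crossed)
})

test_that("across-morning grouping uses one fasted value per morning", {
  sch <- risk_scheme()
  df <- data.frame(
    participant = "A",
    timestamp = c("2024-03-01 06:30", "2024-03-01 07:30",
                  "2024-03-02 06:30", "2024-03-03 06:30"),
    analyte = "TC", value = c(195, 300, 205, 198),
    fasted = TRUE, stringsAsFactors = FALSE)
  r <- crossing_report(as_lipid_cohort(df), sch,
                       grouping = "across_mornings")
  tc <- r$participants
  expect_equal(tc$n_samples, 3L)  # second 03-01 sample dropped
  expect_equal(tc$max, 205)       # the 300 never enters
  expect_true(tc$crossed)
})

test_that("participants with fewer than two qualifying samples are excluded
           from denominators", {
  sch <- risk_scheme()
  df <- data.frame(
    participant = c("A", "A", "B"),
    timestamp = c("2024-03-01 06:00", "2024-03-01 12:00",
                  "2024-03-01 06:00"),
    analyte = "TC", value = c(180, 210, 190), stringsAsFactors = FALSE)
  r <- crossing_report(as_lipid_cohort(df), sch, grouping = "within_day")
  expect_equal(r$cohort$n[r$cohort$analyte == "TC"], 1L)
})

test_that("variability summary reports the median and SD of per-participant
           ranges, matching a sort-based recomputation", {
  sch <- risk_scheme()
  ranges <- c(10, 20, 90)
  rows <- do.call(rbind, lapply(seq_along(ranges), function(i)
    data.frame(participant = sprintf("S%d", i),
               timestamp = sprintf("2024-03-01 %02d:00", c(6, 18)),
               analyte = "TC", value = c(150, 150 + ranges[i]),
               stringsAsFactors = FALSE)))
  r <- crossing_report(as_lipid_cohort(rows), sch)
  vs <- variability_summary(r)
  expect_equal(vs$median_range, 20)
  expect_equal(vs$sd_range, sd(ranges))

  # order-statistics oracle on a simulated cohort
  sim <- generate_cohort(sim_config(n_participants = 9L, seed = 5L))
  rr <- crossing_report(sim$cohort, sch)
  vv <- variability_summary(rr)
  for (a in vv$analyte) {
    rng <- rr$participants$range[rr$participants$analyte == a]
    s <- sort(rng)
    med <- if (length(s) %% 2) s[(length(s) + 1) / 2] else
      mean(s[length(s) / 2 + 0:1])
    expect_equal(vv$median_range[vv$analyte == a], med)
  }
})
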