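test_that("CSV round trip is the identity on valid cohorts", {
  df <- data.frame(
    participant = rep(c("A", "B"), each = 5),
    timestamp = rep(sprintf("2024-03-01 %02d:00", seq(6, 22, by = 4)), 2),
    analyte = rep(c("TC", "TG", "HDL", "TC", "TG"), 2),
    value = c(180.5, 150, 55, 210, 160, 190, 145, 60.2, 200, 175),
    fasted = rep(c(TRUE, FALSE), 5),
    hunger = c(0:3, NA, 2, NA, NA, 1, 3),
    cycle_day = c(NA, NA, 14, NA, NA, 3, NA, NA, NA, NA),
    pair_id = c("q1", "q1", NA, NA, NA, NA, NA, NA, "q2", "q2"),
    reference_value = c(NA, NA, NA, 205, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  x <- as_lipid_cohort(df)
  expect_s3_class(x, "lipid_cohort")
  expect_equal(nrow(x), 10L)
  expect_equal(nrow(attr(x, "rejects")), 0L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(x, path)
  y <- read_samples(path)
  expect_equal(as.data.frame(y), as.data.frame(x),
               ignore_attr = "provenance")
})

test_that("empty cohorts write a header-only file that reads back empty", {
  x <- as_lipid_cohort(data.frame(participant = character(),
                                  timestamp = character(),
                                  analyte = character(),
                                  value = numeric()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(x, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_samples(path)), 0L)
})

test_that("invariant-violating rows are rejected with reasons", {
  df <- data.frame(
    participant = "A",
    timestamp = c("2024-03-01 06:00", "2024-03-01 07:00",
                  "2024-03-01 08:00", "2024-03-01 09:00",
                  "not-a-time", "2024-03-01 11:00", "2024-03-01 06:00"),
    analyte = c("TC", "TC", "LDL", "TC", "TC", "TC", "TC"),
    value = c(180, -5, 190, 2500, 180, 190, 180),
    stringsAsFactors = FALSE)
  x <- suppressMessages(as_lipid_cohort(df))
  rej <- attr(x, "rejects")
  expect_equal(nrow(x), 2L)  # rows 1 and 6 survive
  expect_setequal(rej$row, c(2L, 3L, 4L, 5L, 7L))
  expect_true(any(grepl("unsupported analyte", rej$reason)))
  expect_true(any(grepl("unparseable timestamp", rej$reason)))
  expect_true(any(grepl("outside \\(0, 2000\\)", rej$reason)))
  expect_true(any(grepl("duplicate", rej$reason)))
})

test_that("a missing required column is a configuration error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant,when,analyte,value\nA,2024-03-01 06:00,TC,180",
             path)
  expect_error(read_samples(path), "timestamp")
  expect_s3_class(
    read_samples(path, cohort_dialect(timestamp = "when")), "lipid_cohort")
})

test_that("fasted-morning filter keeps the earliest qualifying sample per
           analyte per day with a half-open window", {
  df <- data.frame(
    participant = "A",
    timestamp = c("2024-03-01 07:30", "2024-03-01 07:45",  # same morning
                  "2024-03-01 08:00",                       # boundary, out
                  "2024-03-02 06:00",                       # second day
                  "2024-03-02 07:00",                       # non-fasted
                  "2024-03-03 09:00"),                      # outside window
    analyte = "TC",
    value = c(180, 185, 190, 200, 210, 220),
    fasted = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  x <- as_lipid_cohort(df)
  f <- filter_fasted_morning(x, time_window(6, 8))
  expect_equal(f$value, c(180, 200))
  # idempotent
  expect_equal(as.data.frame(filter_fasted_morning(f, time_window(6, 8))),
               as.data.frame(f))
})

test_that("fasted windows must end by noon", {
  x <- hour_cohort(7, 180, fasted = TRUE)
  expect_error(filter_fasted_morning(x, time_window(10, 13)),
               "12:00")
})

test_that("within-day slices apply the minimum-sample threshold and
           partition the input", {
  df <- data.frame(
    participant = "A",
    timestamp = c(sprintf("2024-03-01 %02d:00", c(6, 12, 18)),  # 3 samples
                  sprintf("2024-03-02 %02d:00", c(6, 12, 18)),  # + 24:00
                  "2024-03-03 00:00"),
    analyte = "TC", value = 150 + 1:7, stringsAsFactors = FALSE)
  x <- as_lipid_cohort(df)

  s4 <- within_day_slices(x, min_samples = 4, analyte = "TC")
  expect_length(s4, 1L)  # only day 2 (its 24:00 sample counts toward it)
  expect_equal(nrow(s4[[1]]), 4L)
  expect_equal(nrow(attr(s4, "dropped")), 1L)

  s3 <- within_day_slices(x, min_samples = 3, analyte = "TC")
  expect_length(s3, 2L)
  # partition: union of slices == input, no overlap
  pooled <- do.call(rbind, lapply(s3, as.data.frame))
  expect_equal(sort(pooled$value), sort(x$value))

  expect_error(within_day_slices(x, min_samples = 1), ">= 2")
})

test_that("a 24:00 sample belongs to the ending day", {
  df <- data.frame(participant = "A",
                   timestamp = c("2024-03-01 18:00", "2024-03-02 00:00"),
                   analyte = "TC", value = c(150, 160),
                   stringsAsFactors = FALSE)
  x <- as_lipid_cohort(df)
  s <- within_day_slices(x, min_samples = 2, analyte = "TC")
  expect_length(s, 1L)
  expect_equal(names(s), "A/2024-03-01")
})
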