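day_with_wear <- function(w, subject = "s", date = "2020-01-01") {
  minute_series(subject, date, c(rep(80, w), rep(NA, 1440 - w)))
}

test_that("wear minutes count present slots before imputation", {
  expect_identical(wear_minutes(flat_day()), 1440L)
  expect_identical(wear_minutes(day_with_wear(1200)), 1200L)
  expect_identical(wear_minutes(day_with_wear(0)), 0L)
})

test_that("the 80% daily threshold is 1152 minutes and compliance is monotone", {
  expect_identical(compliance_threshold_minutes(0.8), 1152L)
  expect_true(is_compliant(day_with_wear(1152)))
  expect_false(is_compliant(day_with_wear(1151)))
  expect_true(is_compliant(flat_day(), daily_fraction = 1.0))
  # monotone in wear minutes
  w <- sort(sample(0:1440, 25))
  flags <- vapply(w, function(x) is_compliant(day_with_wear(x)), TRUE)
  expect_true(all(diff(as.integer(flags)) >= 0))
})

make_summary <- function(counts_by_subject) {
  data.frame(
    subject_id = names(counts_by_subject),
    least_compliant_semester_count = vapply(counts_by_subject, min, 0),
    stringsAsFactors = FALSE)
}

test_that("cohort selection keeps subjects strictly above the semester floor", {
  s <- make_summary(list(a = c(60, 55, 50, 52), b = c(60, 49, 60, 60),
                         c = c(0, 90, 90, 90)))
  expect_identical(select_cohort(s, 49), "a")
  expect_identical(select_cohort(s, 49, comparator = ">="), c("a", "b"))
  # invariant to subject ordering
  expect_identical(select_cohort(s[c(3, 1, 2), ], 49), "a")
})

test_that("compliance summary counts per semester, 0 for empty semesters", {
  cal <- study_calendar(c("2020-01", "2020-02"), period = 2,
                        semesters = data.frame(
                          name = c("s1", "s2"),
                          start = c("2020-01-01", "2020-02-01"),
                          end = c("2020-02-01", "2020-03-01")))
  days <- list(day_with_wear(1200, "a", "2020-01-05"),
               day_with_wear(1200, "a", "2020-01-06"),
               day_with_wear(100, "a", "2020-02-05"),
               day_with_wear(1200, "b", "2020-02-05"))
  cs <- compliance_summary(days, cal)
  sem <- cs$semesters
  expect_identical(sem$compliant_days[sem$subject_id == "a"], c(2L, 0L))
  # b has no day at all in s1 -> counts 0
  expect_identical(sem$compliant_days[sem$subject_id == "b"], c(0L, 1L))
  expect_identical(cs$subjects$least_compliant_semester_count, c(0L, 0L))
  # enrollment window excludes b's empty first semester
  cs2 <- compliance_summary(days, cal, enrollment = data.frame(
    subject_id = "b", start = "2020-02-01", end = "2020-03-01"))
  expect_identical(
    cs2$subjects$least_compliant_semester_count[cs2$subjects$subject_id == "b"],
    1L)
})

test_that("excluded break days never count toward semester compliance", {
  cal <- study_calendar(c("2020-01", "2020-02"), period = 2,
                        excluded_ranges = data.frame(start = "2020-01-06",
                                                     end = "2020-01-08"),
                        semesters = data.frame(name = "s1",
                                               start = "2020-01-01",
                                               end = "2020-03-01"))
  days <- list(day_with_wear(1200, "a", "2020-01-05"),
               day_with_wear(1200, "a", "2020-01-06"),
               day_with_wear(1200, "a", "2020-01-07"))
  cs <- compliance_summary(days, cal)
  expect_identical(cs$subjects$least_compliant_semester_count, 1L)
})

test_that("wear-threshold sweep counts days at or above each fraction", {
  fr <- c(0.95, 0.85, 0.85, 0.75, 0.75, 0.75, 0.5, 0.5, 0.2, 0.0)
  days <- lapply(seq_along(fr), function(i) {
    day_with_wear(round(fr[i] * 1440), sprintf("s%02d", i))
  })
  sweep <- wear_threshold_sweep(days)
  expect_equal(sweep$threshold, seq(1, 0, by = -0.1))
  # frozen from brute-force counting of fractions >= threshold
  expect_identical(sweep$eligible_days,
                   c(0L, 1L, 3L, 6L, 6L, 8L, 8L, 8L, 9L, 9L, 10L))
  expect_equal(sweep$cumulative_fraction, sweep$eligible_days / 10)
  # monotone nondecreasing as threshold decreases; threshold 0 catches all
  expect_true(all(diff(sweep$eligible_days) >= 0))
  expect_identical(sweep$eligible_days[11L], 10L)
  # all days fully worn -> full count everywhere
  full <- lapply(1:3, function(i) flat_day(subject = paste0("f", i)))
  expect_true(all(wear_threshold_sweep(full)$eligible_days == 3L))
  expect_error(wear_threshold_sweep(list()), "no days")
})

test_that("sweep counts match a brute-force recount on random wear patterns", {
  set.seed(42)
  days <- lapply(1:40, function(i) day_with_wear(sample(0:1440, 1),
                                                 sprintf("r%02d", i)))
  sweep <- wear_threshold_sweep(days)
  frac <- vapply(days, wear_minutes, 0L) / 1440
  for (k in seq_len(nrow(sweep))) {
    n <- 0L
    for (f in frac) if (f >= sweep$threshold[k] - 1e-9) n <- n + 1L
    expect_identical(sweep$eligible_days[k], n)
  }
})

test_that("gap-length profile is the run-length encoding of missingness", {
  hr <- rep(80, 1440)
  hr[11:15] <- NA  # slots 10..14
  hr[101] <- NA    # slot 100
  d <- minute_series("s", "2020-01-01", hr)
  expect_setequal(gap_length_profile(list(d)), c(5L, 1L))
  expect_identical(gap_length_profile(list(flat_day())), integer(0))
  allna <- minute_series("s", "2020-01-01", rep(NA_real_, 1440))
  expect_identical(gap_length_profile(list(allna)), 1440L)
  # pooling across days
  expect_identical(sort(gap_length_profile(list(d, allna))),
                   c(1L, 5L, 1440L))
})
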