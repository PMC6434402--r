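two_month_cal <- function() {
  study_calendar(c("2020-01", "2020-02", "2020-03"), period = 2)
}

test_that("monthly panel normalizes by compliant days only", {
  cal <- two_month_cal()
  prof <- data.frame(
    subject_id = "a",
    date = as.Date(c("2020-01-01", "2020-01-02", "2020-01-03",
                     "2020-02-10", "2020-03-01")),
    compliant = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    target_minutes = c(10L, 20L, 30L, 500L, 45L))
  panel <- monthly_panel(prof, cal)
  expect_identical(nrow(panel), 3L)
  expect_equal(panel$normalized[panel$month == "2020-01"], 20)  # 60/3
  # noncompliant days contribute to neither numerator nor denominator
  expect_identical(panel$compliant_days[panel$month == "2020-02"], 0L)
  expect_true(is.na(panel$normalized[panel$month == "2020-02"]))
  # a single compliant day stands alone
  expect_equal(panel$normalized[panel$month == "2020-03"], 45)
  expect_identical(attr(panel, "period"), 2L)
})

test_that("excluded-range days are dropped from the panel", {
  cal <- study_calendar(c("2020-01", "2020-02"), period = 2,
                        excluded_ranges = data.frame(start = "2020-01-10",
                                                     end = "2020-01-20"))
  prof <- data.frame(
    subject_id = "a",
    date = as.Date(c("2020-01-05", "2020-01-15")),
    compliant = c(TRUE, TRUE), target_minutes = c(10L, 100L))
  panel <- monthly_panel(prof, cal)
  expect_equal(panel$normalized[panel$month == "2020-01"], 10)
  expect_identical(panel$compliant_days[panel$month == "2020-01"], 1L)
})

test_that("decomposition recovers closed forms: periodic, linear, constant", {
  p <- c(5, 9, 1, 7, 3, 8, 2, 6, 4)
  x <- rep(p, 2)  # pure period-9 pattern over 18 months
  dec <- seasonal_decompose_additive(x, 9)
  defined <- !is.na(dec$trend)
  expect_identical(sum(defined), 10L)
  expect_equal(dec$trend[defined], rep(mean(p), 10), tolerance = 1e-9)
  expect_equal(dec$figure, p - mean(p), tolerance = 1e-9)
  expect_equal(dec$remainder[defined], rep(0, 10), tolerance = 1e-9)

  t <- 1:18
  lin <- 3 + 0.7 * t
  dec2 <- seasonal_decompose_additive(lin, 9)
  d2 <- !is.na(dec2$trend)
  expect_equal(dec2$trend[d2], lin[d2], tolerance = 1e-9)
  expect_equal(max(abs(dec2$seasonal)), 0, tolerance = 1e-9)

  dec3 <- seasonal_decompose_additive(rep(4, 18), 9)
  d3 <- !is.na(dec3$trend)
  expect_equal(dec3$trend[d3], rep(4, sum(d3)), tolerance = 1e-12)
  expect_equal(dec3$seasonal, rep(0, 18), tolerance = 1e-12)
  expect_equal(dec3$remainder[d3], rep(0, sum(d3)), tolerance = 1e-12)
})

test_that("decomposition satisfies the additive identity and zero-sum season", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(18:40, 1)
    period <- sample(c(3, 5, 7, 9), 1)
    if (n < 2 * period) next
    x <- rnorm(n, 50, 10) + 0.3 * seq_len(n)
    dec <- seasonal_decompose_additive(x, period)
    defined <- !is.na(dec$trend)
    expect_equal(dec$trend[defined] + dec$seasonal[defined] +
                   dec$remainder[defined], x[defined], tolerance = 1e-9)
    expect_equal(sum(dec$figure), 0, tolerance = 1e-9)
  }
  expect_error(seasonal_decompose_additive(rnorm(17), 9), "too short")
})

test_that("decomposition matches the classical reference implementation", {
  set.seed(8)
  x <- 20 + 0.5 * (1:27) + rep(c(3, -1, 4, 0, -6), length.out = 27) +
    rnorm(27, 0, 2)
  dec <- seasonal_decompose_additive(x, 5)
  ref <- stats::decompose(ts(x, frequency = 5), type = "additive")
  expect_equal(dec$trend, as.numeric(ref$trend), tolerance = 1e-9)
  expect_equal(dec$seasonal, as.numeric(ref$seasonal), tolerance = 1e-9)
})

test_that("interior missing months are interpolated and flagged", {
  x <- c(1:8, NA, 10:18)
  dec <- seasonal_decompose_additive(x, 9)
  expect_identical(which(dec$interpolated), 9L)
  expect_equal(dec$observed[9], 9)
  expect_error(seasonal_decompose_additive(c(NA, 2:18), 9), "trim")
})

test_that("Mann-Kendall matches brute force on exhaustive small cases", {
  expect_identical(suppressWarnings(mann_kendall(c(1, 2, 3)))$s, 3L)
  mk <- suppressWarnings(mann_kendall(c(5, 5, 5, 5)))
  expect_identical(mk$s, 0L)
  expect_identical(mk$z, 0)
  expect_identical(mk$p_value, 1)
  expect_identical(suppressWarnings(mann_kendall(c(3, 1, 2)))$s, -1L)
  expect_error(mann_kendall(c(1, 2)), ">= 3")
  # random spot-check against the pair-enumeration oracle (full grid runs in
  # the acceptance suite)
  set.seed(17)
  for (i in 1:200) {
    x <- sample(0:3, sample(3:12, 1), replace = TRUE)
    got <- suppressWarnings(mann_kendall(x))
    want <- oracle_mann_kendall(x)
    expect_identical(got$s, as.integer(want$s))
    expect_equal(got$var_s, want$var_s)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("Mann-Kendall is antisymmetric and label-invariant under scaling", {
  set.seed(23)
  for (i in 1:50) {
    x <- rnorm(12)  # tie-free almost surely
    a <- suppressWarnings(mann_kendall(x))
    b <- suppressWarnings(mann_kendall(rev(x)))
    expect_identical(a$s, -b$s)
    expect_equal(a$z, -b$z)
    expect_equal(a$p_value, b$p_value)
    # positive scaling preserves the label; negation swaps it
    la <- classify_trend(a, 0.05)
    ls <- classify_trend(suppressWarnings(mann_kendall(3.7 * x)), 0.05)
    ln <- classify_trend(suppressWarnings(mann_kendall(-x)), 0.05)
    expect_identical(ls, la)
    expect_identical(ln, switch(la, positive = "negative",
                                negative = "positive", none = "none"))
  }
})

test_that("trend labels follow sign and significance", {
  fake <- function(s, p) structure(list(s = s, p_value = p),
                                   class = "mann_kendall")
  expect_identical(classify_trend(fake(40, 0.01)), "positive")
  expect_identical(classify_trend(fake(-40, 0.01)), "negative")
  expect_identical(classify_trend(fake(5, 0.30)), "none")
  expect_identical(classify_trend(fake(0, 0.001)), "none")
})

test_that("trend extraction labels drifting and constant subjects correctly", {
  cal <- default_study_calendar()
  months <- seq_along(cal$months)
  mk_panel <- function(subject, normalized) {
    structure(data.frame(subject_id = subject, month = cal$months,
                         month_index = months,
                         target_sum = normalized * 20,
                         compliant_days = 20L, normalized = normalized),
              period = 9L, class = c("monthly_panel", "data.frame"))
  }
  season <- rep(c(4, 2, 0, -2, -6, 0, 2, 0, 0), 2)
  up <- mk_panel("up", 20 + 2.5 * months + season)
  flat <- mk_panel("flat", rep(30, 18))
  res <- extract_trends(rbind(up, flat), period = 9)
  expect_identical(res$label[res$subject_id == "up"], "positive")
  expect_identical(res$label[res$subject_id == "flat"], "none")
  expect_identical(res$n_trend, c(10L, 10L))
  # too-short series labeled none with a warning
  short <- mk_panel("short", c(1:5, rep(NA, 13)))
  expect_warning(res2 <- extract_trends(short, period = 9), "too short")
  expect_identical(res2$label, "none")
})

test_that("compliance-balance diagnostic behaves under null and shift", {
  cal <- two_month_cal()
  set.seed(77)
  mk_rows <- function(subject, days) {
    data.frame(subject_id = subject, month = cal$months, month_index = 1:3,
               target_sum = 10, compliant_days = days, normalized = 1)
  }
  panel <- do.call(rbind, lapply(1:30, function(i) {
    mk_rows(sprintf("s%02d", i), sample(20:28, 3, replace = TRUE))
  }))
  labels <- data.frame(subject_id = sprintf("s%02d", 1:30),
                       label = rep(c("positive", "negative", "none"), 10))
  null_res <- check_compliance_balance(panel, labels)
  expect_s3_class(null_res, "compliance_balance")
  expect_gt(null_res$p_value, 0.05)
  # a strongly shifted group is detected
  panel2 <- panel
  shift <- labels$subject_id[labels$label == "negative"]
  panel2$compliant_days[panel2$subject_id %in% shift] <- 5L
  expect_true(check_compliance_balance(panel2, labels)$significant)
  # fewer than two groups is an error
  expect_error(check_compliance_balance(panel, data.frame(
    subject_id = labels$subject_id, label = "none")), ">= 2")
})
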