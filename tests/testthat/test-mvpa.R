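test_that("Karvonen zone arithmetic and bounds", {
  z <- karvonen_zone(60, 190, 0.5)
  expect_equal(z$hrr, 130)
  expect_equal(z$zone_min, 125)
  # y -> 1 boundary collapses onto max HR
  expect_equal(karvonen_zone(60, 190, 1.0)$zone_min, 190)
  expect_error(karvonen_zone(70, 70), "rhr < max_hr")
  expect_error(karvonen_zone(80, 240), "230")
  expect_error(karvonen_zone(60, 190, 0), "y must be")
})

test_that("daily zone parameters combine age rule, inputs and the RHR fallback", {
  d <- flat_day(60)
  z <- daily_zone_params(d, age = 18, rhr = 62)
  expect_equal(z$max_hr, 202)
  expect_equal(z$zone_min, (202 - 62) * 0.5 + 62)  # 132
  # fallback estimator: mean of the lowest 30 present minutes
  z2 <- daily_zone_params(d, age = 18)
  expect_equal(z2$rhr, 60)
  # explicit max_hr overrides 220 - age
  expect_equal(daily_zone_params(d, age = 18, rhr = 62, max_hr = 190)$max_hr,
               190)
  few <- minute_series("s", "2020-01-01", c(rep(70, 10), rep(NA, 1430)))
  expect_error(daily_zone_params(few, age = 18), "resting HR")
})

test_that("RHR estimator averages the lowest present minutes", {
  hr <- c(rep(50, 10), rep(60, 20), rep(120, 1410))
  d <- minute_series("s", "2020-01-01", hr)
  expect_equal(estimate_rhr(d, 30), (10 * 50 + 20 * 60) / 30)
})

test_that("zone membership is inclusive at the minimum and false when missing", {
  z <- karvonen_zone(60, 190, 0.5)  # zone_min 125
  hr <- rep(NA_real_, 1440)
  hr[1:3] <- c(130, 125, 124)
  m <- in_zone_mask(minute_series("s", "2020-01-01", hr), z)
  expect_identical(m[1:4], c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(sum(m), 2L)
})

pad_mask <- function(runs) {
  # runs: alternating in-zone/out-of-zone lengths starting in-zone
  unlist(lapply(seq_along(runs), function(i) rep(i %% 2 == 1, runs[i])))
}

test_that("bout detection: threshold, merging, and both conventions", {
  # 12 consecutive in-zone minutes -> one bout of 12
  b <- detect_bouts(pad_mask(c(12)), 10, 1)
  expect_identical(nrow(b), 1L)
  expect_identical(b$duration, 12L)
  # 9 minutes -> nothing
  expect_identical(nrow(detect_bouts(pad_mask(c(9)), 10, 1)), 0L)
  # 6 + 1-min dip + 6 -> merged, elapsed 13
  b <- detect_bouts(pad_mask(c(6, 1, 6)), 10, 1)
  expect_identical(b$duration, 13L)
  expect_identical(b$in_zone_minutes, 12L)
  # 6 + 2-min dip + 6 -> no bout
  expect_identical(nrow(detect_bouts(pad_mask(c(6, 2, 6)), 10, 1)), 0L)
  # strict convention merges only already-qualifying bouts
  expect_identical(nrow(detect_bouts(pad_mask(c(6, 1, 6)), 10, 1,
                                     merge_first = FALSE)), 0L)
  b <- detect_bouts(pad_mask(c(10, 1, 10)), 10, 1, merge_first = FALSE)
  expect_identical(b$duration, 21L)
  # chains collapse left to right: 6-1-6-1-6 -> one bout of 20
  b <- detect_bouts(pad_mask(c(6, 1, 6, 1, 6)), 10, 1)
  expect_identical(b$duration, 20L)
  # merge_gap 0 disables bridging
  expect_identical(nrow(detect_bouts(pad_mask(c(6, 1, 6)), 10, 0)), 0L)
})

test_that("bout detection agrees with the brute-force enumerator", {
  set.seed(2024)
  for (i in 1:2000) {
    mask <- random_mask()
    merge_first <- i %% 2 == 0
    got <- detect_bouts(mask, 10, 1, merge_first = merge_first)
    want <- oracle_bouts(mask, 10, 1, merge_first = merge_first)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
  # wider merge gaps and lower thresholds too
  for (i in 1:500) {
    mask <- random_mask()
    mb <- sample(2:12, 1)
    mg <- sample(0:3, 1)
    got <- detect_bouts(mask, mb, mg, merge_first = i %% 2 == 0)
    want <- oracle_bouts(mask, mb, mg, merge_first = i %% 2 == 0)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("bout detection is invariant to out-of-zone padding and monotone in zone_min", {
  set.seed(5)
  for (i in 1:50) {
    mask <- random_mask(n = 100)
    base <- detect_bouts(mask, 10, 1)
    padded <- detect_bouts(c(rep(FALSE, 7), mask, rep(FALSE, 11)), 10, 1)
    expect_identical(nrow(padded), nrow(base))
    if (nrow(base) > 0) {
      expect_identical(padded$start, base$start + 7L)
      expect_identical(padded$duration, base$duration)
    }
  }
  # lowering zone_min never decreases target minutes; disabling the merge
  # rule never increases them
  hr <- 90 + 50 * sin(2 * pi * (0:1439) / 240) + rnorm(1440, 0, 8)
  d <- minute_series("s", "2020-01-01", pmin(pmax(hr, 30), 240))
  zones <- seq(80, 140, by = 5)
  tm <- vapply(zones, function(zm) {
    z <- karvonen_zone(50, 200, (zm - 50) / 150)
    target_minutes(detect_bouts(in_zone_mask(d, z), 10, 1))
  }, 0L)
  expect_true(all(diff(tm) <= 0))  # zones ordered increasing -> tm decreasing
  z <- karvonen_zone(50, 200, 0.4)
  m <- in_zone_mask(d, z)
  expect_lte(target_minutes(detect_bouts(m, 10, 0)),
             target_minutes(detect_bouts(m, 10, 1)))
})

test_that("target minutes sum disjoint bouts under both accounting rules", {
  b <- detect_bouts(pad_mask(c(12, 5, 15)), 10, 1)
  expect_identical(target_minutes(b), 27L)
  expect_identical(target_minutes(detect_bouts(pad_mask(c(5)), 10, 1)), 0L)
  expect_identical(target_minutes(detect_bouts(rep(TRUE, 1440), 10, 1)), 1440L)
  # bridged minute counts under elapsed convention, not under in-zone
  b <- detect_bouts(pad_mask(c(6, 1, 6)), 10, 1)
  expect_identical(target_minutes(b, count_bridged = TRUE), 13L)
  expect_identical(target_minutes(b, count_bridged = FALSE), 12L)
  overlapping <- data.frame(start = c(0L, 5L), end = c(10L, 15L),
                            duration = c(10L, 10L),
                            in_zone_minutes = c(10L, 10L))
  expect_error(target_minutes(overlapping), "overlap")
})

test_that("day profiles assemble wear, zones and targets per subject-day", {
  hr <- rep(70, 1440)
  hr[601:615] <- 140  # 15-minute bout for zone_min <= 140
  d1 <- minute_series("a", "2020-01-01", hr)
  d2 <- minute_series("a", "2020-01-02", c(rep(70, 1000), rep(NA, 440)))
  dp <- compute_day_profiles(list(d1, d2), ages = c(a = 20), rhr = data.frame(
    subject_id = "a", rhr = 60))
  p <- dp$profiles
  expect_identical(p$wear_minutes, c(1440L, 1000L))
  expect_identical(p$compliant, c(TRUE, FALSE))
  expect_equal(p$zone_min, rep((200 - 60) * 0.5 + 60, 2))  # 130
  expect_identical(p$target_minutes, c(15L, 0L))
  expect_identical(dp$bouts$start, 600L)
  expect_identical(dp$bouts$end, 615L)
})
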