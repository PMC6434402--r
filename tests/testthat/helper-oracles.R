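# Independent brute-force references used to check the package's
# implementations. These deliberately use naive algorithms (explicit loops,
# index-set manipulation) so they share no code path with the package.

# Mann-Kendall by explicit pair enumeration
oracle_mann_kendall <- function(x) {
  x <- unname(as.numeric(x[!is.na(x)]))
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  counts <- as.numeric(table(x))
  v <- (n * (n - 1) * (2 * n + 5) -
          sum(counts * (counts - 1) * (2 * counts + 5))) / 18
  z <- if (v == 0 || s == 0) 0 else if (s > 0) (s - 1) / sqrt(v) else (s + 1) / sqrt(v)
  list(s = s, var_s = v, z = z, p_value = min(1, 2 * pnorm(-abs(z))))
}

# bout detection by explicit run scanning and iterative index-set merging
oracle_bouts <- function(mask, min_bout = 10L, merge_gap = 1L,
                         merge_first = TRUE) {
  runs <- list()
  cur <- integer(0)
  for (t in seq_along(mask)) {
    if (mask[t]) {
      cur <- c(cur, t)
    } else if (length(cur) > 0L) {
      runs[[length(runs) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur) > 0L) runs[[length(runs) + 1L]] <- cur
  merge_pass <- function(runs) {
    i <- 1L
    while (i < length(runs)) {
      a <- runs[[i]]
      b <- runs[[i + 1L]]
      sep <- min(b) - max(a) - 1L
      gap <- if (sep > 0L) (max(a) + 1L):(min(b) - 1L) else integer(0)
      if (sep <= merge_gap && all(!mask[gap])) {
        runs[[i]] <- c(a, gap, b)  # bridged minutes become part of the bout
        runs[[i + 1L]] <- NULL
      } else {
        i <- i + 1L
      }
    }
    runs
  }
  if (merge_first) {
    if (merge_gap > 0L) runs <- merge_pass(runs)
    runs <- Filter(function(r) length(r) >= min_bout, runs)
  } else {
    runs <- Filter(function(r) length(r) >= min_bout, runs)
    if (merge_gap > 0L) runs <- merge_pass(runs)
  }
  if (length(runs) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      duration = integer(), in_zone_minutes = integer()))
  }
  data.frame(
    start = vapply(runs, function(r) min(r) - 1L, 0L),
    end = vapply(runs, max, 0L),
    duration = vapply(runs, length, 0L),
    in_zone_minutes = vapply(runs, function(r) sum(mask[r]), 0L))
}

random_mask <- function(n = NULL, density = NULL) {
  if (is.null(n)) n <- sample(1:200, 1L)
  if (is.null(density)) density <- runif(1L)
  runif(n) < density
}

# a day whose HR is an arbitrary function of the 0-based slot
make_day <- function(f, subject = "T", date = "2020-01-01") {
  slot <- 0:1439
  minute_series(subject, date, f(slot))
}

flat_day <- function(value = 70, ...) make_day(function(s) rep(value, 1440), ...)
linear_day <- function(a = 60, b = 0.05, ...) make_day(function(s) a + b * s, ...)
sin_day <- function(mean = 90, amp = 40, ...) {
  make_day(function(s) mean + amp * sin(2 * pi * s / 1440), ...)
}

# small two-subject-friendly synthetic config for fast tests
tiny_synth <- function(n_subjects = 2L, seed = 101L, ...) {
  synth_config(n_subjects = n_subjects, seed = seed, ...)
}

write_hr_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("subject_id,timestamp,heart_rate", lines), path)
  path
}
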