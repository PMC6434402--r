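#' Personalized target heart zone (Karvonen heart-rate reserve)
#'
#' Heart-rate reserve HRR = max HR − resting HR; target zone minimum =
#' HRR × y + RHR. The intensity constant y defaults to 0.5, the level
#' conventionally recommended for moderate-vigorous activity.
#'
#' @param rhr resting heart rate, beats/min (25 ≤ rhr < max_hr).
#' @param max_hr maximal heart rate, beats/min (≤ 230).
#' @param y intensity fraction in (0, 1\].
#' @return a list of class `zone_params` with `rhr`, `max_hr`, `y`, `hrr`,
#'   `zone_min`.
#' @export
karvonen_zone <- function(rhr, max_hr, y = 0.5) {
  if (!is.finite(rhr) || !is.finite(max_hr) || rhr >= max_hr) {
    stopf("need rhr < max_hr, got rhr=%s max_hr=%s", rhr, max_hr)
  }
  if (rhr < HR_MIN || max_hr > 230) {
    stopf("need 25 <= rhr < max_hr <= 230, got rhr=%s max_hr=%s", rhr, max_hr)
  }
  if (!is.finite(y) || y <= 0 || y > 1) stopf("y must be in (0, 1], got %s", y)
  hrr <- max_hr - rhr
  structure(list(rhr = rhr, max_hr = max_hr, y = y, hrr = hrr,
                 zone_min = hrr * y + rhr),
            class = "zone_params")
}

#' @export
print.zone_params <- function(x, ...) {
  cat(sprintf("zone_params: rhr %.1f, max_hr %.1f, hrr %.1f, y %.2f -> zone_min %.1f bpm\n",
              x$rhr, x$max_hr, x$hrr, x$y, x$zone_min))
  invisible(x)
}

#' Estimate resting heart rate from a day's recordings
#'
#' Mean of the lowest `n` present minute values — a simple fallback when no
#' explicit resting-HR input is available.
#'
#' @param day a [minute_series()].
#' @param n number of lowest minutes to average (default 30).
#' @return resting HR in beats/min.
#' @export
estimate_rhr <- function(day, n = 30L) {
  stopifnot(inherits(day, "minute_series"))
  present <- day$hr[!is.na(day$hr)]
  if (length(present) < n) {
    stopf("cannot estimate resting HR: only %d present minutes (< %d) on %s/%s",
          length(present), n, day$subject_id, format(day$date))
  }
  if (length(present) == n) return(mean(present))
  # partial sort: the n smallest values, order within them irrelevant
  mean(sort(present, partial = n)[seq_len(n)])
}

#' Target heart zone for one subject-day
#'
#' Zones are recomputed per day so that resting-HR changes over a long study
#' move the zone with them. Maximal HR defaults to the age-predicted
#' 220 − age unless supplied explicitly; resting HR comes from `rhr` when
#' given, otherwise from the lowest-minutes estimator ([estimate_rhr()]).
#'
#' @param day a [minute_series()].
#' @param age subject age in years (needed unless `max_hr` is supplied).
#' @param rhr optional known resting HR for this day, beats/min.
#' @param max_hr optional explicit maximal HR, beats/min.
#' @param y intensity fraction (default 0.5).
#' @param rhr_lowest_n minutes averaged by the fallback estimator.
#' @return a `zone_params` object (see [karvonen_zone()]).
#' @export
daily_zone_params <- function(day, age = NULL, rhr = NULL, max_hr = NULL,
                              y = 0.5, rhr_lowest_n = 30L) {
  if (is.null(max_hr)) {
    if (is.null(age)) stopf("need age (for 220 - age) or explicit max_hr")
    max_hr <- 220 - age
  }
  if (is.null(rhr)) rhr <- estimate_rhr(day, n = rhr_lowest_n)
  karvonen_zone(rhr, max_hr, y)
}

#' In-zone mask of a subject-day
#'
#' A minute is in the target zone when a (possibly imputed) heart rate is
#' present and at or above the zone minimum (inclusive; the zone has no
#' upper cutoff). Missing minutes are out of zone.
#'
#' @param day a [minute_series()] (typically after [impute_linear()]).
#' @param zone a `zone_params` object.
#' @return logical vector of length 1440.
#' @export
in_zone_mask <- function(day, zone) {
  stopifnot(inherits(day, "minute_series"), inherits(zone, "zone_params"))
  !is.na(day$hr) & day$hr >= zone$zone_min
}

#' Detect MVPA bouts in an in-zone mask
#'
#' A bout is a run of at least `min_bout` consecutive in-zone minutes. To
#' tolerate brief recording errors or momentary dips below the zone, runs
#' separated by at most `merge_gap` out-of-zone minutes are combined before
#' the duration filter (`merge_first = TRUE`, the default); chains collapse
#' in a single pass. The stricter reading — only runs already of qualifying
#' length are merged — is available with `merge_first = FALSE`. Bridged
#' out-of-zone minutes count toward elapsed duration.
#'
#' @param mask logical vector (in-zone per minute); any length is accepted.
#' @param min_bout minimum elapsed bout duration in minutes (default 10).
#' @param merge_gap maximum out-of-zone separation to bridge (default 1;
#'   0 disables merging).
#' @param merge_first merge runs before (`TRUE`, default) or after the
#'   duration filter.
#' @return data frame with 0-based half-open columns `start`, `end`,
#'   `duration` (= end − start, elapsed) and `in_zone_minutes`
#'   (duration minus bridged minutes).
#' @export
detect_bouts <- function(mask, min_bout = 10L, merge_gap = 1L,
                         merge_first = TRUE) {
  stopifnot(is.logical(mask), !anyNA(mask))
  min_bout <- as.integer(min_bout)
  merge_gap <- as.integer(merge_gap)
  bout_frame <- function(start, end, duration, in_zone_minutes) {
    # constructed directly: this runs once per subject-day
    structure(list(start = start, end = end, duration = duration,
                   in_zone_minutes = in_zone_minutes),
              class = "data.frame",
              row.names = .set_row_names(length(start)))
  }
  empty <- bout_frame(integer(), integer(), integer(), integer())
  if (length(mask) == 0L || !any(mask)) return(empty)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (merge_first && merge_gap > 0L) {
    # interior out-of-zone runs short enough to bridge become in-zone;
    # one pass suffices since remaining FALSE runs stay longer than the gap
    bridge <- !r$values & r$lengths <= merge_gap &
      seq_along(r$values) != 1L & seq_along(r$values) != length(r$values)
    r$values[bridge] <- TRUE
    merged <- rle(inverse.rle(r))
    ends2 <- cumsum(merged$lengths)
    starts2 <- ends2 - merged$lengths + 1L
    keep <- merged$values & merged$lengths >= min_bout
    bs <- starts2[keep]
    be <- ends2[keep]
  } else {
    keep <- r$values & r$lengths >= min_bout
    bs <- starts[keep]
    be <- ends[keep]
    if (merge_gap > 0L && length(bs) > 1L) {
      # merge qualifying bouts separated by an entirely out-of-zone stretch
      # of at most merge_gap minutes, left to right (chains keep merging)
      i <- 1L
      while (i < length(bs)) {
        between <- (be[i] + 1L):(bs[i + 1L] - 1L)
        sep <- bs[i + 1L] - be[i] - 1L
        if (sep <= merge_gap && (sep == 0L || !any(mask[between]))) {
          be[i] <- be[i + 1L]
          bs <- bs[-(i + 1L)]
          be <- be[-(i + 1L)]
        } else {
          i <- i + 1L
        }
      }
    }
  }
  if (length(bs) == 0L) return(empty)
  bout_frame(start = bs - 1L, end = be, duration = be - bs + 1L,
             in_zone_minutes = vapply(seq_along(bs),
                                      function(i) sum(mask[bs[i]:be[i]]), 0L))
}

#' Daily target minutes from detected bouts
#'
#' Sum of bout durations. With `count_bridged = FALSE` the out-of-zone
#' minutes bridged inside a bout are excluded from the sum.
#'
#' @param bouts data frame from [detect_bouts()].
#' @param count_bridged count bridged minutes toward the total
#'   (elapsed-time convention, default `TRUE`).
#' @return integer minutes.
#' @export
target_minutes <- function(bouts, count_bridged = TRUE) {
  if (nrow(bouts) == 0L) return(0L)
  o <- order(bouts$start)
  if (any(bouts$end[o][-nrow(bouts)] > bouts$start[o][-1L])) {
    stopf("bouts overlap")
  }
  if (count_bridged) sum(bouts$duration) else sum(bouts$in_zone_minutes)
}

#' Per-day profiles: wear, compliance, zones, bouts, target minutes
#'
#' Runs the per-day stages in order for every subject-day: wear minutes and
#' the compliance flag are computed before imputation; gaps on compliant days
#' are filled by capped linear interpolation; the personalized zone is
#' recomputed per day; bouts are detected on the in-zone mask and aggregated
#' into daily target minutes. On days where the zone cannot be determined
#' (no resting-HR input and fewer present minutes than the estimator needs)
#' the zone and target columns are `NA`.
#'
#' @param days list of [minute_series()].
#' @param ages named numeric vector (by subject id), a single number applied
#'   to all subjects, or a data frame `subject_id`, `age`.
#' @param rhr optional resting-HR input: a data frame `subject_id`, `rhr`
#'   (subject-level) or `subject_id`, `date`, `rhr` (per day).
#' @param max_hr optional explicit maximal HR (named vector or scalar);
#'   overrides the 220 − age rule.
#' @param y intensity fraction (default 0.5).
#' @param daily_fraction compliance wear fraction (default 0.8).
#' @param max_gap_minutes imputation cap (default 150).
#' @param min_bout,merge_gap,merge_first,count_bridged bout-detection
#'   settings, see [detect_bouts()] and [target_minutes()].
#' @param impute_noncompliant also impute days below the compliance
#'   threshold (default `FALSE`: imputation is restricted to days with at
#'   most the compliant amount of missingness, so long stretches are never
#'   fabricated).
#' @param rhr_lowest_n minutes averaged by the resting-HR estimator.
#' @return a list of class `day_profiles` with `profiles` (one row per
#'   subject-day: subject_id, date, wear_minutes, compliant, rhr, max_hr,
#'   zone_min, target_minutes, n_bouts) and `bouts` (subject_id, date,
#'   start, end, duration, in_zone_minutes).
#' @export
compute_day_profiles <- function(days, ages = NULL, rhr = NULL, max_hr = NULL,
                                 y = 0.5, daily_fraction = 0.8,
                                 max_gap_minutes = 150L, min_bout = 10L,
                                 merge_gap = 1L, merge_first = TRUE,
                                 count_bridged = TRUE,
                                 impute_noncompliant = FALSE,
                                 rhr_lowest_n = 30L) {
  if (is.data.frame(ages)) ages <- stats::setNames(ages$age, ages$subject_id)
  lookup <- function(tbl, subj) {
    if (is.null(tbl)) return(NULL)
    if (length(tbl) == 1L && is.null(names(tbl))) return(tbl[[1L]])
    v <- unname(tbl[subj])
    if (is.na(v)) NULL else v
  }
  rhr_lookup <- function(subj, date) {
    if (is.null(rhr)) return(NULL)
    stopifnot(is.data.frame(rhr))
    rows <- rhr[rhr$subject_id == subj, , drop = FALSE]
    if ("date" %in% names(rows)) {
      rows <- rows[as.Date(rows$date) == date, , drop = FALSE]
    }
    if (nrow(rows) == 0L) NULL else rows$rhr[1L]
  }
  n <- length(days)
  p_subject <- character(n)
  p_date <- rep(as.Date(NA), n)
  p_wear <- integer(n)
  p_compliant <- logical(n)
  p_rhr <- rep(NA_real_, n)
  p_maxhr <- rep(NA_real_, n)
  p_zone <- rep(NA_real_, n)
  p_target <- rep(NA_integer_, n)
  p_nbouts <- rep(NA_integer_, n)
  bout_rows <- vector("list", n)
  for (i in seq_along(days)) {
    d <- days[[i]]
    wm <- wear_minutes(d)
    compliant <- wm >= compliance_threshold_minutes(daily_fraction)
    p_subject[i] <- d$subject_id
    p_date[i] <- d$date
    p_wear[i] <- wm
    p_compliant[i] <- compliant
    imp <- if (compliant || impute_noncompliant) {
      impute_linear(d, max_gap_minutes)
    } else {
      d
    }
    zone <- tryCatch(
      daily_zone_params(imp,
                        age = lookup(ages, d$subject_id),
                        rhr = rhr_lookup(d$subject_id, d$date),
                        max_hr = lookup(max_hr, d$subject_id),
                        y = y, rhr_lowest_n = rhr_lowest_n),
      error = function(e) NULL)
    if (is.null(zone)) next
    bouts <- detect_bouts(in_zone_mask(imp, zone), min_bout = min_bout,
                          merge_gap = merge_gap, merge_first = merge_first)
    p_rhr[i] <- zone$rhr
    p_maxhr[i] <- zone$max_hr
    p_zone[i] <- zone$zone_min
    p_target[i] <- target_minutes(bouts, count_bridged)
    p_nbouts[i] <- nrow(bouts)
    if (nrow(bouts) > 0L) bout_rows[[i]] <- bouts
  }
  profiles <- data.frame(
    subject_id = p_subject, date = p_date, wear_minutes = p_wear,
    compliant = p_compliant, rhr = p_rhr, max_hr = p_maxhr,
    zone_min = p_zone, target_minutes = p_target, n_bouts = p_nbouts,
    stringsAsFactors = FALSE)
  profiles <- profiles[order(profiles$subject_id, profiles$date), ]
  rownames(profiles) <- NULL
  nb <- vapply(bout_rows, function(b) if (is.null(b)) 0L else nrow(b), 0L)
  if (sum(nb) == 0L) {
    bouts_df <- data.frame(subject_id = character(), date = as.Date(character()),
                           start = integer(), end = integer(),
                           duration = integer(), in_zone_minutes = integer())
  } else {
    bouts_df <- cbind(
      data.frame(subject_id = rep(p_subject, nb), date = rep(p_date, nb),
                 stringsAsFactors = FALSE),
      do.call(rbind, bout_rows))
    bouts_df <- bouts_df[order(bouts_df$subject_id, bouts_df$date,
                               bouts_df$start), ]
    rownames(bouts_df) <- NULL
  }
  structure(list(profiles = profiles, bouts = bouts_df),
            class = "day_profiles")
}
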