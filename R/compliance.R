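#' Worn minutes of a subject-day
#'
#' Wear is defined as the presence of a heart-rate recording at that minute;
#' counted before any imputation.
#'
#' @param day a [minute_series()].
#' @return integer count of present minutes in \[0, 1440\].
#' @export
wear_minutes <- function(day) {
  stopifnot(inherits(day, "minute_series"))
  sum(!is.na(day$hr))
}

#' Daily wear threshold in minutes
#'
#' `round(fraction * 1440)`: at the default fraction 0.80 this is 1152
#' minutes (19.2 h, commonly quoted as 19 hours).
#'
#' @param daily_fraction fraction of the day that must be worn, in (0, 1\].
#' @return integer minutes.
#' @export
compliance_threshold_minutes <- function(daily_fraction = 0.8) {
  stopifnot(daily_fraction > 0, daily_fraction <= 1)
  as.integer(round(daily_fraction * MINUTES_PER_DAY))
}

#' Is a subject-day compliant?
#'
#' A day is compliant when its wear minutes reach the daily fraction
#' threshold (default 80% of 1440 = 1152 minutes).
#'
#' @param day a [minute_series()].
#' @param daily_fraction fraction of the day that must be worn (default 0.8).
#' @return logical.
#' @export
is_compliant <- function(day, daily_fraction = 0.8) {
  wear_minutes(day) >= compliance_threshold_minutes(daily_fraction)
}

#' Per-day, per-semester and per-subject compliance summary
#'
#' Computes wear minutes and the compliance flag for every subject-day,
#' counts compliant days per subject and semester (days inside excluded
#' calendar ranges do not count), and records each subject's least compliant
#' semester. Semesters with no recorded day count 0 unless an enrollment
#' window excludes them for that subject.
#'
#' @param days list of [minute_series()].
#' @param calendar a [study_calendar()] with semesters defined.
#' @param daily_fraction daily wear fraction threshold (default 0.8).
#' @param enrollment optional data frame `subject_id`, `start`, `end`
#'   (half-open dates): semesters ending before `start` or starting after
#'   `end` are not counted against that subject.
#' @return a list of class `compliance_summary` with elements `days`
#'   (subject_id, date, wear_minutes, compliant, semester, excluded),
#'   `semesters` (subject_id, semester, compliant_days) and `subjects`
#'   (subject_id, least_compliant_semester_count).
#' @export
compliance_summary <- function(days, calendar, daily_fraction = 0.8,
                               enrollment = NULL) {
  stopifnot(inherits(calendar, "study_calendar"))
  if (is.null(calendar$semesters)) stopf("calendar has no semesters defined")
  subject_id <- vapply(days, function(d) d$subject_id, "")
  date <- as.Date(vapply(days, function(d) format(d$date), ""))
  wear <- vapply(days, wear_minutes, 0L)
  day_df <- data.frame(
    subject_id = subject_id, date = date, wear_minutes = wear,
    compliant = wear >= compliance_threshold_minutes(daily_fraction),
    semester = semester_of(date, calendar),
    excluded = date_in_ranges(date, calendar$excluded_ranges),
    stringsAsFactors = FALSE)
  subjects <- sort(unique(subject_id))
  sem <- calendar$semesters
  grid <- expand.grid(subject_id = subjects, semester = sem$name,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts <- day_df[day_df$compliant & !day_df$excluded &
                     !is.na(day_df$semester), c("subject_id", "semester")]
  if (nrow(counts) > 0L) {
    agg <- stats::aggregate(list(compliant_days = rep(1L, nrow(counts))),
                            counts, FUN = sum)
  } else {
    agg <- data.frame(subject_id = character(), semester = character(),
                      compliant_days = integer(), stringsAsFactors = FALSE)
  }
  sem_df <- merge(grid, agg, by = c("subject_id", "semester"), all.x = TRUE)
  sem_df$compliant_days[is.na(sem_df$compliant_days)] <- 0L
  if (!is.null(enrollment)) {
    enrollment <- as.data.frame(enrollment)
    enrollment$start <- as.Date(enrollment$start)
    enrollment$end <- as.Date(enrollment$end)
    keep <- rep(TRUE, nrow(sem_df))
    for (i in seq_len(nrow(sem_df))) {
      e <- enrollment[enrollment$subject_id == sem_df$subject_id[i], ]
      if (nrow(e) == 1L) {
        s <- sem[sem$name == sem_df$semester[i], ]
        keep[i] <- s$end > e$start && s$start < e$end
      }
    }
    sem_df <- sem_df[keep, , drop = FALSE]
  }
  least <- stats::aggregate(
    list(least_compliant_semester_count = sem_df$compliant_days),
    list(subject_id = sem_df$subject_id), FUN = min)
  least <- least[order(least$subject_id), , drop = FALSE]
  rownames(least) <- NULL
  structure(list(days = day_df,
                 semesters = sem_df[order(sem_df$subject_id, sem_df$semester), ],
                 subjects = least),
            class = "compliance_summary")
}

#' Select the analysis cohort by least-compliant-semester count
#'
#' Keeps subjects whose minimum compliant-day count over semesters exceeds
#' `min_days_per_semester` (strictly, by default, i.e. "above" the
#' threshold; set `comparator = ">="` for an inclusive rule).
#'
#' @param summary a [compliance_summary()], or its `subjects` data frame.
#' @param min_days_per_semester integer threshold (default 49).
#' @param comparator `">"` (default) or `">="`.
#' @return sorted character vector of retained subject ids.
#' @export
select_cohort <- function(summary, min_days_per_semester = 49L,
                          comparator = c(">", ">=")) {
  comparator <- match.arg(comparator)
  df <- if (inherits(summary, "compliance_summary")) summary$subjects else summary
  stopifnot(is.data.frame(df),
            all(c("subject_id", "least_compliant_semester_count") %in% names(df)))
  keep <- if (comparator == ">") {
    df$least_compliant_semester_count > min_days_per_semester
  } else {
    df$least_compliant_semester_count >= min_days_per_semester
  }
  sort(unique(df$subject_id[keep]))
}

#' Wear-time threshold sweep
#'
#' For each candidate minimum daily wear fraction, counts the subject-days
#' whose wear fraction reaches it — the curve used to pick the compliance
#' threshold (its inflection point). Counts are nondecreasing as the
#' threshold decreases.
#'
#' @param days list of [minute_series()].
#' @param thresholds decreasing vector of wear fractions
#'   (default `seq(1, 0, by = -0.1)`, i.e. 100% down to 0% in steps of 10).
#' @return data frame with columns `threshold`, `eligible_days`,
#'   `cumulative_fraction` (= eligible/total).
#' @export
wear_threshold_sweep <- function(days, thresholds = seq(1, 0, by = -0.1)) {
  if (length(days) == 0L) stopf("no days supplied")
  frac <- vapply(days, wear_minutes, 0L) / MINUTES_PER_DAY
  # small tolerance so that e.g. fraction 0.7 counts at threshold 0.7 despite
  # floating-point representation of seq() steps
  counts <- vapply(thresholds, function(th) sum(frac >= th - 1e-9), 0L)
  data.frame(threshold = thresholds, eligible_days = counts,
             cumulative_fraction = counts / length(days))
}

#' Pooled lengths of within-day missing runs
#'
#' Run-length profile of missing minutes across all subject-days (gaps
#' spanning midnight are split at the day boundary by construction). Used to
#' parameterize the imputation benchmark and the synthetic gap model.
#'
#' @param days list of [minute_series()].
#' @return integer vector of maximal missing-run lengths (possibly empty).
#' @export
gap_length_profile <- function(days) {
  out <- lapply(days, function(d) {
    r <- rle(is.na(d$hr))
    r$lengths[r$values]
  })
  as.integer(unlist(out))
}
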