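#' Construct a study calendar
#'
#' The calendar defines which calendar months are under observation, which
#' date ranges are excluded (scheduled breaks, when wear compliance is not
#' representative), how the study is partitioned into semesters, and the
#' seasonal period used for decomposition (the number of observed months per
#' repeating cycle, e.g. 9 months per academic year).
#'
#' @param months character vector of observed months as `"YYYY-MM"`, strictly
#'   increasing. Months absent from this list (e.g. summer months) are simply
#'   not observed.
#' @param excluded_ranges optional data frame with columns `start`, `end`
#'   (coercible to [Date]); half-open intervals `[start, end)` of days removed
#'   from consideration. Ranges must not overlap.
#' @param semesters optional data frame with columns `name`, `start`, `end`
#'   (half-open date intervals) naming the semester partition used by the
#'   compliance cohort filter.
#' @param period integer seasonal period for decomposition; must satisfy
#'   `2 <= period <= length(months)`.
#' @return an object of class `study_calendar`.
#' @seealso [load_calendar()], [default_study_calendar()]
#' @export
study_calendar <- function(months, excluded_ranges = NULL, semesters = NULL,
                           period = 9L) {
  if (length(months) < 2L) stopf("calendar needs at least 2 months")
  first_days <- as.Date(paste0(months, "-01"))
  if (anyNA(first_days)) {
    stopf("months: unparseable month(s): %s",
          paste(months[is.na(first_days)], collapse = ", "))
  }
  if (any(diff(first_days) <= 0)) {
    stopf("months: must be strictly increasing")
  }
  period <- as.integer(period)
  if (is.na(period) || period < 2L || period > length(months)) {
    stopf("period: must satisfy 2 <= period <= number of observed months (%d), got %s",
          length(months), period)
  }
  if (!is.null(excluded_ranges)) {
    excluded_ranges <- as.data.frame(excluded_ranges)
    if (!all(c("start", "end") %in% names(excluded_ranges))) {
      stopf("excluded_ranges: needs columns start, end")
    }
    excluded_ranges$start <- as.Date(excluded_ranges$start)
    excluded_ranges$end <- as.Date(excluded_ranges$end)
    if (anyNA(excluded_ranges$start) || anyNA(excluded_ranges$end)) {
      stopf("excluded_ranges: unparseable dates")
    }
    if (any(excluded_ranges$end <= excluded_ranges$start)) {
      stopf("excluded_ranges: end must be after start (half-open [start, end))")
    }
    o <- order(excluded_ranges$start)
    excluded_ranges <- excluded_ranges[o, , drop = FALSE]
    if (nrow(excluded_ranges) > 1L) {
      overlap <- excluded_ranges$start[-1L] <
        excluded_ranges$end[-nrow(excluded_ranges)]
      if (any(overlap)) stopf("excluded_ranges: ranges overlap")
    }
    rownames(excluded_ranges) <- NULL
  }
  if (!is.null(semesters)) {
    semesters <- as.data.frame(semesters)
    if (!all(c("name", "start", "end") %in% names(semesters))) {
      stopf("semesters: needs columns name, start, end")
    }
    semesters$start <- as.Date(semesters$start)
    semesters$end <- as.Date(semesters$end)
    if (anyNA(semesters$start) || anyNA(semesters$end)) {
      stopf("semesters: unparseable dates")
    }
    if (any(semesters$end <= semesters$start)) {
      stopf("semesters: end must be after start")
    }
  }
  cal <- structure(
    list(months = as.character(months),
         month_starts = first_days,
         excluded_ranges = excluded_ranges,
         semesters = semesters,
         period = period),
    class = "study_calendar")
  # every observed month must retain at least one non-excluded day
  for (i in seq_along(cal$months)) {
    days <- month_dates(cal, i)
    if (length(days) == 0L) {
      stopf("months: month %s has no day outside excluded_ranges",
            cal$months[i])
    }
  }
  cal
}

# all non-excluded dates of observed month i (or of all months)
month_dates <- function(cal, i) {
  start <- cal$month_starts[i]
  nxt <- seq(start, by = "1 month", length.out = 2L)[2L]
  days <- seq(start, nxt - 1L, by = "1 day")
  days[!date_in_ranges(days, cal$excluded_ranges)]
}

#' All observed, non-excluded dates of a study calendar
#' @param calendar a [study_calendar()].
#' @return a `Date` vector in increasing order.
#' @export
calendar_dates <- function(calendar) {
  stopifnot(inherits(calendar, "study_calendar"))
  do.call(c, lapply(seq_along(calendar$months), month_dates, cal = calendar))
}

#' Map dates to observed-month index (NA for unobserved or excluded dates)
#' @param dates a `Date` vector.
#' @param calendar a [study_calendar()].
#' @return integer vector of 1-based positions in `calendar$months`.
#' @export
month_index <- function(dates, calendar) {
  stopifnot(inherits(calendar, "study_calendar"))
  idx <- match(month_key(dates), calendar$months)
  idx[date_in_ranges(dates, calendar$excluded_ranges)] <- NA_integer_
  idx
}

#' Map dates to semester names (NA outside any semester)
#' @param dates a `Date` vector.
#' @param calendar a [study_calendar()] with semesters defined.
#' @return character vector of semester names.
#' @export
semester_of <- function(dates, calendar) {
  stopifnot(inherits(calendar, "study_calendar"))
  sem <- calendar$semesters
  out <- rep(NA_character_, length(dates))
  if (is.null(sem)) return(out)
  for (i in seq_len(nrow(sem))) {
    hit <- dates >= sem$start[i] & dates < sem$end[i]
    out[hit] <- sem$name[i]
  }
  out
}

#' Load a study calendar from a YAML or JSON configuration file
#'
#' The file must provide `months` (vector of `"YYYY-MM"`), `period`, and
#' optionally `excluded_ranges` (list of `{start, end}`) and `semesters`
#' (list of `{name, start, end}`). All invariants of [study_calendar()] are
#' enforced; violations are reported with the offending field name.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [study_calendar()].
#' @export
load_calendar <- function(path) {
  if (!file.exists(path)) stopf("calendar file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$months)) stopf("months: missing from calendar config")
  if (is.null(cfg$period)) stopf("period: missing from calendar config")
  to_df <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  study_calendar(months = unlist(cfg$months),
                 excluded_ranges = to_df(cfg$excluded_ranges),
                 semesters = to_df(cfg$semesters),
                 period = cfg$period)
}

#' Write a study calendar to a YAML file
#' @param calendar a [study_calendar()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calendar <- function(calendar, path) {
  stopifnot(inherits(calendar, "study_calendar"))
  row_list <- function(df) {
    if (is.null(df)) return(NULL)
    lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      lapply(r, function(v) if (inherits(v, "Date")) format(v) else as.vector(v))
    })
  }
  yaml::write_yaml(list(months = calendar$months,
                        excluded_ranges = row_list(calendar$excluded_ranges),
                        semesters = row_list(calendar$semesters),
                        period = calendar$period),
                   path)
  invisible(path)
}

#' Two academic years of nine observed months each
#'
#' August 2015 through April 2017 with May, June and July 2016 unobserved:
#' 18 observed months, four semesters of roughly four and a half months, and
#' a seasonal period of 9 (one academic year).
#'
#' @return a [study_calendar()].
#' @export
default_study_calendar <- function() {
  months <- c(sprintf("2015-%02d", 8:12), sprintf("2016-%02d", 1:4),
              sprintf("2016-%02d", 8:12), sprintf("2017-%02d", 1:4))
  semesters <- data.frame(
    name = c("fall-2015", "spring-2016", "fall-2016", "spring-2017"),
    start = as.Date(c("2015-08-01", "2016-01-01", "2016-08-01", "2017-01-01")),
    end = as.Date(c("2016-01-01", "2016-05-01", "2017-01-01", "2017-05-01")),
    stringsAsFactors = FALSE)
  study_calendar(months, semesters = semesters, period = 9L)
}

#' @export
print.study_calendar <- function(x, ...) {
  cat(sprintf("study_calendar: %d observed months (%s .. %s), period %d\n",
              length(x$months), x$months[1L], x$months[length(x$months)],
              x$period))
  if (!is.null(x$excluded_ranges)) {
    cat(sprintf("  excluded ranges: %d\n", nrow(x$excluded_ranges)))
  }
  if (!is.null(x$semesters)) {
    cat(sprintf("  semesters: %s\n", paste(x$semesters$name, collapse = ", ")))
  }
  invisible(x)
}
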