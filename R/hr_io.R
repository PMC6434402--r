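#' Construct a one-day minute-resolution heart-rate series
#'
#' A subject-day holds exactly 1440 heart-rate slots (slot k = minute k of the
#' local clock day, 0-based); minutes without a recording are `NA`. Present
#' values must lie in \[25, 250\] beats/min.
#'
#' @param subject_id opaque subject identifier (character scalar).
#' @param date the calendar date (coercible to [Date]).
#' @param hr numeric vector of length 1440, `NA` marking missing minutes.
#' @return an object of class `minute_series`.
#' @export
minute_series <- function(subject_id, date, hr) {
  subject_id <- as.character(subject_id)
  date <- as.Date(date)
  if (length(subject_id) != 1L || is.na(subject_id) || !nzchar(subject_id)) {
    stopf("subject_id must be a non-empty string")
  }
  if (length(date) != 1L || is.na(date)) stopf("date must be a single date")
  hr <- as.numeric(hr)
  if (length(hr) != MINUTES_PER_DAY) {
    stopf("hr must have exactly %d slots, got %d", MINUTES_PER_DAY, length(hr))
  }
  bad <- !is.na(hr) & (hr < HR_MIN | hr > HR_MAX)
  if (any(bad)) {
    stopf("heart rate outside [%d, %d] bpm at slot(s) %s (subject %s, %s)",
          HR_MIN, HR_MAX, paste(utils::head(which(bad) - 1L, 5L), collapse = ", "),
          subject_id, format(date))
  }
  structure(list(subject_id = subject_id, date = date, hr = hr),
            class = "minute_series")
}

#' @export
print.minute_series <- function(x, ...) {
  cat(sprintf("minute_series: subject %s, %s, %d/%d minutes present\n",
              x$subject_id, format(x$date), sum(!is.na(x$hr)),
              MINUTES_PER_DAY))
  invisible(x)
}

#' Read minute-level heart-rate records from delimited text
#'
#' Expects columns `subject_id`, `timestamp` (ISO-8601, minute resolution;
#' seconds are truncated) and `heart_rate` (alias `heart_rate_bpm` accepted).
#' Each (subject, date) pair becomes one [minute_series()]; minutes absent
#' from the file become missing markers. Nothing is dropped silently: an
#' unparseable timestamp, a heart rate outside \[25, 250\] bpm, or a duplicate
#' (subject, minute) row is an error naming the offending line.
#'
#' @param path path to a CSV (or TSV, see `sep`) file.
#' @param sep field separator; guessed from the file extension by default
#'   (`.tsv`/`.txt` → tab, otherwise comma).
#' @return a list of [minute_series()], sorted by subject then date, with
#'   attribute `n_rows` (rows ingested, equal to the total present minutes).
#' @export
read_minute_hr <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  hr_col <- intersect(c("heart_rate", "heart_rate_bpm"), names(df))[1L]
  need <- c("subject_id", "timestamp")
  if (is.na(hr_col) || !all(need %in% names(df))) {
    stopf("expected columns subject_id, timestamp, heart_rate; found: %s",
          paste(names(df), collapse = ", "))
  }
  if (nrow(df) == 0L) return(structure(list(), n_rows = 0L))
  # +1 for the header: report physical line numbers
  line_no <- seq_len(nrow(df)) + 1L
  ts <- as.POSIXct(rep(NA_real_, nrow(df)), tz = "UTC",
                   origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(df$timestamp[todo], fmt, tz = "UTC"))
  }
  if (anyNA(ts)) {
    i <- which(is.na(ts))[1L]
    stopf("line %d: unparseable timestamp '%s'", line_no[i], df$timestamp[i])
  }
  hr <- suppressWarnings(as.numeric(df[[hr_col]]))
  if (anyNA(hr)) {
    i <- which(is.na(hr))[1L]
    stopf("line %d: unparseable heart rate '%s'", line_no[i], df[[hr_col]][i])
  }
  bad <- hr < HR_MIN | hr > HR_MAX
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf("line %d: heart rate %s outside [%d, %d] bpm", line_no[i], hr[i],
          HR_MIN, HR_MAX)
  }
  lt <- as.POSIXlt(ts)
  date <- as.Date(ts)
  slot <- lt$hour * 60L + lt$min  # seconds truncated
  key <- paste(df$subject_id, format(date), slot)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stopf("line %d: duplicate minute for subject %s at %s slot %d",
          line_no[i], df$subject_id[i], format(date[i]), slot[i])
  }
  day_key <- paste(df$subject_id, format(date), sep = "|")
  out <- lapply(split(seq_len(nrow(df)), day_key), function(idx) {
    v <- rep(NA_real_, MINUTES_PER_DAY)
    v[slot[idx] + 1L] <- hr[idx]
    minute_series(df$subject_id[idx[1L]], date[idx[1L]], v)
  })
  ord <- order(vapply(out, function(d) d$subject_id, ""),
               vapply(out, function(d) format(d$date), ""))
  structure(out[ord], n_rows = nrow(df))
}

#' Write minute-level heart-rate records as delimited text
#'
#' Inverse of [read_minute_hr()]: one row per present minute, columns
#' `subject_id,timestamp,heart_rate`.
#'
#' @param days a list of [minute_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_minute_hr <- function(days, path) {
  rows <- lapply(days, function(d) {
    present <- which(!is.na(d$hr))
    if (length(present) == 0L) return(NULL)
    slot <- present - 1L
    data.frame(subject_id = d$subject_id,
               timestamp = sprintf("%sT%02d:%02d:00", format(d$date),
                                   slot %/% 60L, slot %% 60L),
               heart_rate = d$hr[present],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(subject_id = character(), timestamp = character(),
                     heart_rate = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-day profiles to CSV
#'
#' Writes one row per subject-day (wear minutes, compliance flag, resting and
#' maximal HR, zone minimum, target minutes, bout count). The table
#' round-trips losslessly through [read_day_profiles()].
#'
#' @param profiles a data frame of day profiles (e.g.
#'   `compute_day_profiles(...)$profiles`), or the list returned by
#'   [compute_day_profiles()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_day_profiles <- function(profiles, path) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      !is.null(profiles$profiles)) {
    profiles <- profiles$profiles
  }
  stopifnot(is.data.frame(profiles))
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-day profiles written by [write_day_profiles()]
#' @param path CSV path.
#' @return a data frame with `subject_id` as character, `date` as [Date] and
#'   `compliant` as logical.
#' @export
read_day_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  if ("compliant" %in% names(df)) df$compliant <- as.logical(df$compliant)
  df
}
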