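#' Monthly panel of normalized target minutes
#'
#' Downsamples daily target minutes to one value per observed calendar month:
#' the sum of target minutes over the subject's compliant days in that month,
#' divided by the number of compliant days — normalizing months shortened by
#' breaks and differences in how often subjects wore the device. Only
#' compliant days contribute; days inside excluded calendar ranges are
#' dropped; a month with no compliant day yields a missing value.
#'
#' @param profiles day-profile data frame (or [compute_day_profiles()]
#'   output) with columns subject_id, date, compliant, target_minutes.
#' @param calendar a [study_calendar()].
#' @return data frame of class `monthly_panel` with one row per
#'   subject × observed month: `subject_id`, `month` ("YYYY-MM"),
#'   `month_index`, `target_sum`, `compliant_days`, `normalized`; attribute
#'   `period` carries the calendar's seasonal period.
#' @export
monthly_panel <- function(profiles, calendar) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      !is.null(profiles$profiles)) {
    profiles <- profiles$profiles
  }
  stopifnot(inherits(calendar, "study_calendar"), is.data.frame(profiles))
  need <- c("subject_id", "date", "compliant", "target_minutes")
  stopifnot(all(need %in% names(profiles)))
  profiles$date <- as.Date(profiles$date)
  mi <- month_index(profiles$date, calendar)
  use <- !is.na(mi) & profiles$compliant & !is.na(profiles$target_minutes)
  subjects <- sort(unique(profiles$subject_id))
  grid <- expand.grid(subject_id = subjects,
                      month_index = seq_along(calendar$months),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (any(use)) {
    agg <- stats::aggregate(
      list(target_sum = profiles$target_minutes[use],
           compliant_days = rep(1L, sum(use))),
      list(subject_id = profiles$subject_id[use], month_index = mi[use]),
      FUN = sum)
  } else {
    agg <- data.frame(subject_id = character(), month_index = integer(),
                      target_sum = numeric(), compliant_days = integer())
  }
  panel <- merge(grid, agg, by = c("subject_id", "month_index"), all.x = TRUE)
  panel$compliant_days[is.na(panel$compliant_days)] <- 0L
  panel$target_sum[panel$compliant_days == 0L] <- NA_real_
  panel$month <- calendar$months[panel$month_index]
  panel$normalized <- ifelse(panel$compliant_days > 0L,
                             panel$target_sum / panel$compliant_days,
                             NA_real_)
  panel <- panel[order(panel$subject_id, panel$month_index),
                 c("subject_id", "month", "month_index", "target_sum",
                   "compliant_days", "normalized")]
  rownames(panel) <- NULL
  structure(panel, period = calendar$period, class = c("monthly_panel",
                                                       "data.frame"))
}

#' Classical additive seasonal decomposition
#'
#' observed = trend + seasonal + remainder. The trend is a centered moving
#' average of window `period` (a simple mean for odd periods; the standard
#' half-weighted 2×m window for even periods), undefined at the first and
#' last `floor(period/2)` positions. The seasonal component is the per-phase
#' mean of the detrended series, re-centered to zero mean, repeated across
#' cycles; the remainder is what is left. Interior missing values are
#' pre-filled by linear interpolation across months and flagged.
#'
#' @param x numeric series (e.g. a subject's normalized monthly values);
#'   leading/trailing values must be present.
#' @param period integer seasonal period; `length(x) >= 2 * period` required.
#' @return a list of class `hr_decomposition` with `observed` (after
#'   interior interpolation), `trend`, `seasonal`, `remainder`, `figure`
#'   (one seasonal value per phase), `period` and `interpolated` (logical
#'   flags).
#' @export
seasonal_decompose_additive <- function(x, period) {
  x <- as.numeric(x)
  period <- as.integer(period)
  n <- length(x)
  if (period < 2L) stopf("period must be >= 2")
  if (n < 2L * period) {
    stopf("series too short for decomposition: need >= %d points, got %d",
          2L * period, n)
  }
  interpolated <- rep(FALSE, n)
  if (anyNA(x)) {
    if (is.na(x[1L]) || is.na(x[n])) {
      stopf("leading/trailing values must be present (trim the series first)")
    }
    was_na <- is.na(x)
    x <- as.numeric(zoo::na.approx(x, na.rm = FALSE))
    interpolated <- was_na & !is.na(x)
  }
  half <- period %/% 2L
  w <- if (period %% 2L == 1L) {
    rep(1 / period, period)
  } else {
    c(0.5, rep(1, period - 1L), 0.5) / period
  }
  trend <- as.numeric(stats::filter(x, w, sides = 2))
  detrended <- x - trend
  phase <- ((seq_len(n) - 1L) %% period) + 1L
  figure <- vapply(seq_len(period), function(ph) {
    v <- detrended[phase == ph]
    mean(v, na.rm = TRUE)
  }, 0)
  figure <- figure - mean(figure)
  seasonal <- figure[phase]
  structure(list(observed = x, trend = trend, seasonal = seasonal,
                 remainder = x - trend - seasonal, figure = figure,
                 period = period, interpolated = interpolated),
            class = "hr_decomposition")
}

#' Mann-Kendall test for a monotonic trend
#'
#' S is the sum of `sign(x[j] - x[i])` over all ordered pairs i < j; its
#' variance uses the tie correction
#' `Var(S) = (n(n-1)(2n+5) - sum_t t(t-1)(2t+5)) / 18` over tie groups of
#' size t. Z applies the ±1 continuity correction and the two-sided p-value
#' comes from the standard normal. Missing values are dropped, order
#' preserved; fewer than 3 defined values is an error. The normal
#' approximation is crude below n = 10 (a warning is issued).
#'
#' @param x numeric series.
#' @return a list of class `mann_kendall` with `s`, `var_s`, `z`, `p_value`,
#'   `n`.
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stopf("Mann-Kendall needs >= 3 defined values, got %d", n)
  if (n < 10L) {
    warnf("Mann-Kendall normal approximation is crude for n = %d (< 10)", n)
  }
  d <- sign(outer(x, x, "-"))          # d[i, j] = sign(x[i] - x[j])
  s <- as.integer(-sum(d[upper.tri(d)]))  # sum over i < j of sign(x[j] - x[i])
  tt <- as.numeric(table(x))
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  z <- if (s > 0) {
    (s - 1) / sqrt(var_s)
  } else if (s < 0) {
    (s + 1) / sqrt(var_s)
  } else {
    0
  }
  if (var_s == 0) z <- 0
  structure(list(s = s, var_s = var_s, z = z,
                 p_value = min(1, 2 * stats::pnorm(-abs(z))), n = n),
            class = "mann_kendall")
}

#' @export
print.mann_kendall <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %d, Var(S) = %.2f, Z = %.3f, p = %.4g (n = %d)\n",
              x$s, x$var_s, x$z, x$p_value, x$n))
  invisible(x)
}

#' Label a trend from a Mann-Kendall result
#'
#' `"positive"` if p < alpha and S > 0, `"negative"` if p < alpha and S < 0,
#' otherwise `"none"`.
#'
#' @param mk a [mann_kendall()] result.
#' @param alpha significance level (default 0.05).
#' @return character scalar.
#' @export
classify_trend <- function(mk, alpha = 0.05) {
  stopifnot(inherits(mk, "mann_kendall"))
  if (mk$p_value < alpha && mk$s > 0) return("positive")
  if (mk$p_value < alpha && mk$s < 0) return("negative")
  "none"
}

#' Extract and label each subject's long-term MVPA trend
#'
#' For each subject: the normalized monthly series (leading/trailing missing
#' months trimmed; interior ones linearly interpolated) is decomposed by
#' [seasonal_decompose_additive()], the defined positions of the trend
#' component are tested with [mann_kendall()], and the subject is labeled by
#' [classify_trend()]. Subjects whose series is too short to decompose, or
#' whose defined trend has fewer than 3 points, are labeled `"none"` with a
#' warning.
#'
#' @param panel a [monthly_panel()].
#' @param period seasonal period (default: the panel's attribute).
#' @param alpha significance level (default 0.05).
#' @return data frame with one row per subject: `subject_id`, `n_months`
#'   (defined monthly values), `n_trend` (defined trend points), `s`,
#'   `var_s`, `z`, `p_value`, `label`.
#' @export
extract_trends <- function(panel, period = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(panel))
  if (is.null(period)) period <- attr(panel, "period")
  if (is.null(period)) stopf("period not given and panel carries none")
  res <- lapply(split(panel, panel$subject_id), function(p) {
    p <- p[order(p$month_index), ]
    x <- p$normalized
    row <- data.frame(subject_id = p$subject_id[1L],
                      n_months = sum(!is.na(x)), n_trend = 0L,
                      s = NA_integer_, var_s = NA_real_, z = NA_real_,
                      p_value = NA_real_, label = "none",
                      stringsAsFactors = FALSE)
    def <- which(!is.na(x))
    if (length(def) == 0L) {
      warnf("subject %s: no defined months; labeled none", row$subject_id)
      return(row)
    }
    x <- x[def[1L]:def[length(def)]]  # trim leading/trailing missing months
    if (length(x) < 2L * period) {
      warnf("subject %s: series too short to decompose (%d < %d); labeled none",
            row$subject_id, length(x), 2L * period)
      return(row)
    }
    dec <- seasonal_decompose_additive(x, period)
    tr <- dec$trend[!is.na(dec$trend)]
    row$n_trend <- length(tr)
    if (length(tr) < 3L) {
      warnf("subject %s: defined trend has %d (< 3) points; labeled none",
            row$subject_id, length(tr))
      return(row)
    }
    mk <- suppressWarnings(mann_kendall(tr))
    row$s <- mk$s
    row$var_s <- mk$var_s
    row$z <- mk$z
    row$p_value <- mk$p_value
    row$label <- classify_trend(mk, alpha)
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compliance-balance diagnostic across trend groups
#'
#' Checks that labels do not merely reflect when subjects were compliant:
#' Kruskal-Wallis H-tests (tie-corrected ranks) compare the distribution of
#' compliant days per subject-month across trend labels — pooled over all
#' months, and per month. A non-significant result supports that the groups
#' contributed similar compliance.
#'
#' @param panel a [monthly_panel()].
#' @param trend_results output of [extract_trends()] (columns `subject_id`,
#'   `label`).
#' @param alpha reporting threshold (default 0.05).
#' @return list of class `compliance_balance` with `statistic` (pooled H),
#'   `p_value`, `significant`, `per_month` (month, statistic, p_value), and
#'   `alpha`.
#' @export
check_compliance_balance <- function(panel, trend_results, alpha = 0.05) {
  stopifnot(is.data.frame(panel), is.data.frame(trend_results))
  df <- merge(as.data.frame(panel),
              trend_results[, c("subject_id", "label")], by = "subject_id")
  df <- df[!is.na(df$label), ]
  groups <- unique(df$label)
  if (length(groups) < 2L) {
    stopf("need >= 2 nonempty trend groups, got %d", length(groups))
  }
  kw <- stats::kruskal.test(df$compliant_days, factor(df$label))
  per_month <- do.call(rbind, lapply(split(df, df$month), function(m) {
    if (length(unique(m$label)) < 2L) return(NULL)
    k <- stats::kruskal.test(m$compliant_days, factor(m$label))
    data.frame(month = m$month[1L], statistic = unname(k$statistic),
               p_value = k$p.value, stringsAsFactors = FALSE)
  }))
  if (!is.null(per_month)) rownames(per_month) <- NULL
  structure(list(statistic = unname(kw$statistic), p_value = kw$p.value,
                 significant = kw$p.value < alpha, per_month = per_month,
                 alpha = alpha),
            class = "compliance_balance")
}
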