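#' Pipeline configuration
#'
#' Bundles all stage settings with their defaults resolved. Unknown keys are
#' rejected so a typo in a config file cannot silently fall back to a
#' default.
#'
#' @param ... overrides for: `daily_fraction` (0.8),
#'   `min_days_per_semester` (49), `comparator` (">"), `max_gap_minutes`
#'   (150), `y` (0.5), `min_bout` (10), `merge_gap` (1), `merge_first`
#'   (TRUE), `count_bridged` (TRUE), `rhr_lowest_n` (30), `period` (NULL =
#'   take from the calendar), `alpha` (0.05), `apply_cohort_filter` (TRUE).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(daily_fraction = 0.8, min_days_per_semester = 49L,
              comparator = ">", max_gap_minutes = 150L, y = 0.5,
              min_bout = 10L, merge_gap = 1L, merge_first = TRUE,
              count_bridged = TRUE, rhr_lowest_n = 30L, period = NULL,
              alpha = 0.05, apply_cohort_filter = TRUE)
  over <- list(...)
  if (length(over) > 0L) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L || is.null(names(over)) ||
        any(!nzchar(names(over)))) {
      stopf("unknown pipeline config key(s): %s",
            paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  stopifnot(cfg$daily_fraction > 0, cfg$daily_fraction <= 1,
            cfg$min_days_per_semester >= 0, cfg$comparator %in% c(">", ">="),
            cfg$max_gap_minutes >= 1, cfg$y > 0, cfg$y <= 1,
            cfg$min_bout >= 1, cfg$merge_gap >= 0,
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full trend-extraction pipeline
#'
#' Stages, in order: wear-time compliance summary → cohort selection by
#' least-compliant semester → gap imputation, daily personalized zones and
#' bout detection → monthly normalized panel → seasonal decomposition +
#' Mann-Kendall labeling → compliance-balance diagnostic. Every filter's
#' in/out counts are logged; the run is deterministic (the pipeline itself
#' draws no random numbers).
#'
#' @param days list of [minute_series()] (e.g. from [read_minute_hr()] or
#'   [generate_cohort()]).
#' @param calendar a [study_calendar()].
#' @param ages,rhr,max_hr subject metadata, see [compute_day_profiles()].
#' @param config a [pipeline_config()].
#' @param enrollment optional enrollment windows, see [compliance_summary()].
#' @param out_dir if given, day-profile, monthly-panel and trend-result CSVs
#'   plus the run log are written there.
#' @param verbose emit log lines as messages (default `FALSE`).
#' @return a list of class `pipeline_result` with `compliance`, `cohort`,
#'   `profiles` (a `day_profiles` list), `panel`, `trends`, `balance`
#'   (or `NULL` when fewer than two label groups exist), `config`, and `log`
#'   (character vector).
#' @export
run_pipeline <- function(days, calendar, ages = NULL, rhr = NULL,
                         max_hr = NULL, config = pipeline_config(),
                         enrollment = NULL, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(calendar, "study_calendar"),
            inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    if (verbose) message(line)
    invisible(NULL)
  }
  say("config: %s", paste(sprintf("%s=%s", names(config),
                                  vapply(config, function(v)
                                    paste(format(v), collapse = ","), "")),
                          collapse = " "))
  n_subjects_in <- length(unique(vapply(days, function(d) d$subject_id, "")))
  say("input: %d subject-days from %d subjects", length(days), n_subjects_in)
  if (length(days) == 0L) {
    warnf("empty cohort: no subject-days supplied")
    empty_trends <- data.frame(subject_id = character(), n_months = integer(),
                               n_trend = integer(), s = integer(),
                               var_s = numeric(), z = numeric(),
                               p_value = numeric(), label = character())
    return(structure(list(compliance = NULL, cohort = character(0),
                          profiles = NULL, panel = NULL,
                          trends = empty_trends, balance = NULL,
                          config = config, log = log),
                     class = "pipeline_result"))
  }
  comp <- compliance_summary(days, calendar,
                             daily_fraction = config$daily_fraction,
                             enrollment = enrollment)
  say("compliance: %d/%d subject-days compliant (>= %d min worn)",
      sum(comp$days$compliant), nrow(comp$days),
      compliance_threshold_minutes(config$daily_fraction))
  if (config$apply_cohort_filter) {
    cohort <- select_cohort(comp, config$min_days_per_semester,
                            comparator = config$comparator)
  } else {
    cohort <- sort(unique(comp$days$subject_id))
  }
  say("cohort: %d/%d subjects retained (least compliant semester %s %d days)",
      length(cohort), n_subjects_in, config$comparator,
      config$min_days_per_semester)
  use_days <- days[vapply(days, function(d) d$subject_id %in% cohort, TRUE)]
  profiles <- compute_day_profiles(
    use_days, ages = ages, rhr = rhr, max_hr = max_hr, y = config$y,
    daily_fraction = config$daily_fraction,
    max_gap_minutes = config$max_gap_minutes, min_bout = config$min_bout,
    merge_gap = config$merge_gap, merge_first = config$merge_first,
    count_bridged = config$count_bridged,
    rhr_lowest_n = config$rhr_lowest_n)
  say("profiles: %d subject-days, %d bouts detected",
      nrow(profiles$profiles), nrow(profiles$bouts))
  panel <- monthly_panel(profiles, calendar)
  say("panel: %d subject-months, %d with >= 1 compliant day",
      nrow(panel), sum(panel$compliant_days > 0))
  period <- if (is.null(config$period)) calendar$period else config$period
  trends <- extract_trends(panel, period = period, alpha = config$alpha)
  for (lab in c("positive", "negative", "none")) {
    say("trends: %d subjects labeled %s", sum(trends$label == lab), lab)
  }
  say("counts: subjects_in=%d labeled=%d excluded_by_compliance=%d",
      n_subjects_in, nrow(trends), n_subjects_in - length(cohort))
  balance <- tryCatch(
    check_compliance_balance(panel, trends, alpha = config$alpha),
    error = function(e) {
      say("balance check skipped: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(balance)) {
    say("balance: Kruskal-Wallis H = %.3f, p = %.4g", balance$statistic,
        balance$p_value)
  }
  result <- structure(list(compliance = comp, cohort = cohort,
                           profiles = profiles, panel = panel,
                           trends = trends, balance = balance,
                           config = config, log = log),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_day_profiles(profiles, file.path(out_dir, "day_profiles.csv"))
    utils::write.csv(as.data.frame(panel),
                     file.path(out_dir, "monthly_panel.csv"),
                     row.names = FALSE)
    utils::write.csv(trends, file.path(out_dir, "trend_results.csv"),
                     row.names = FALSE)
    writeLines(result$log, file.path(out_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
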