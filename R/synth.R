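#' Synthetic-cohort configuration
#'
#' Defines the data-generating conditions for a cohort of wearable-HR
#' subjects with known ground truth. Each subject gets a circadian baseline
#' (a sinusoid with its trough in the early morning), scheduled MVPA bouts
#' whose expected daily volume follows `base + drift * month + seasonal`
#' (clamped at zero), device-dropout gaps of 2–150 minutes that are more
#' likely during bouts (mimicking exertion/moisture artifacts), occasional
#' heavily-missing (noncompliant) days, and Gaussian measurement noise.
#'
#' @param n_subjects number of subjects (default 60).
#' @param calendar a [study_calendar()] (default: two nine-month academic
#'   years, [default_study_calendar()]).
#' @param seed integer seed (mandatory); per-subject RNG substreams are
#'   derived from it by stable hashing so outputs do not depend on subject
#'   order.
#' @param age_range integer range of ages, years (default 17–19).
#' @param rhr_mean,rhr_sd resting-HR distribution across subjects, beats/min
#'   (default 62 ± 5).
#' @param circadian_amplitude peak-to-trough amplitude of the daily baseline
#'   sinusoid, beats/min (default 12).
#' @param base_target_minutes expected daily MVPA minutes at month 1 with
#'   zero seasonal offset (default 30).
#' @param drift change in expected daily target minutes per month; a scalar
#'   applied to all subjects or one value per subject. The sign is the
#'   injected ground-truth label (default 0).
#' @param seasonal_profile additive monthly activity offsets, one per phase
#'   of the calendar period, minutes/day; re-centered to zero mean.
#' @param bout_duration_shape,bout_duration_scale gamma parameters of bout
#'   durations, clamped to `[bout_duration_min, bout_duration_max]`.
#' @param bout_duration_min,bout_duration_max bout duration bounds, minutes
#'   (default 10–90; ground-truth bouts are never shorter than 10).
#' @param bout_intensity plateau height above the subject's zone minimum,
#'   beats/min (default 18).
#' @param bout_ramp minutes of sub-zone ramp on each side of a bout
#'   (default 3).
#' @param gaps enable the dropout-gap model (default `TRUE`).
#' @param gap_rate expected gaps per day (Poisson; default 3).
#' @param gap_len_prob probability vector over gap lengths 2..150 minutes
#'   (default: geometric decay, most mass on 2–25 with a tail to 150).
#' @param gap_bout_multiplier relative dropout propensity during bout
#'   minutes (default 4).
#' @param noncompliant_prob probability that a day is heavily missing and
#'   fails the 80% wear threshold (default 0.12).
#' @param noise_sd measurement noise, beats/min (default 3).
#' @param y Karvonen intensity fraction used for the true zones (default 0.5).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 60L,
                         calendar = default_study_calendar(),
                         seed,
                         age_range = c(17L, 19L),
                         rhr_mean = 62, rhr_sd = 5,
                         circadian_amplitude = 12,
                         base_target_minutes = 30,
                         drift = 0,
                         seasonal_profile = NULL,
                         bout_duration_shape = 4, bout_duration_scale = 5,
                         bout_duration_min = 10L, bout_duration_max = 90L,
                         bout_intensity = 18,
                         bout_ramp = 3L,
                         gaps = TRUE,
                         gap_rate = 3,
                         gap_len_prob = NULL,
                         gap_bout_multiplier = 4,
                         noncompliant_prob = 0.12,
                         noise_sd = 3,
                         y = 0.5) {
  if (missing(seed)) stopf("seed is mandatory")
  stopifnot(inherits(calendar, "study_calendar"),
            n_subjects >= 1L, rhr_sd >= 0, circadian_amplitude >= 0,
            base_target_minutes >= 0, bout_duration_min >= 10L,
            bout_duration_max >= bout_duration_min,
            bout_intensity > 0, bout_ramp >= 0L, gap_rate >= 0,
            gap_bout_multiplier >= 1,
            noncompliant_prob >= 0, noncompliant_prob <= 1,
            noise_sd >= 0, y > 0, y < 1)
  if (!(length(drift) %in% c(1L, n_subjects))) {
    stopf("drift must be a scalar or one value per subject")
  }
  if (is.null(seasonal_profile)) {
    # academic-year shape: active early autumn and spring, low around the
    # winter exam/break phase
    base <- c(6, 4, 0, -2, -10, 2, 4, 0, -4)
    seasonal_profile <- rep(base, length.out = calendar$period)
  }
  if (length(seasonal_profile) != calendar$period) {
    stopf("seasonal_profile must have one value per calendar period (%d)",
          calendar$period)
  }
  seasonal_profile <- seasonal_profile - mean(seasonal_profile)
  if (is.null(gap_len_prob)) {
    p <- 0.88^(0:148)  # lengths 2..150
    gap_len_prob <- p / sum(p)
  }
  if (length(gap_len_prob) != 149L || any(gap_len_prob < 0)) {
    stopf("gap_len_prob must be a nonnegative probability vector over 2..150")
  }
  gap_len_prob <- gap_len_prob / sum(gap_len_prob)
  structure(list(
    n_subjects = as.integer(n_subjects), calendar = calendar,
    seed = as.integer(seed), age_range = as.integer(age_range),
    rhr_mean = rhr_mean, rhr_sd = rhr_sd,
    circadian_amplitude = circadian_amplitude,
    base_target_minutes = base_target_minutes,
    drift = rep(drift, length.out = n_subjects),
    seasonal_profile = seasonal_profile,
    bout_duration_shape = bout_duration_shape,
    bout_duration_scale = bout_duration_scale,
    bout_duration_min = as.integer(bout_duration_min),
    bout_duration_max = as.integer(bout_duration_max),
    bout_intensity = bout_intensity, bout_ramp = as.integer(bout_ramp),
    gaps = isTRUE(gaps), gap_rate = gap_rate, gap_len_prob = gap_len_prob,
    gap_bout_multiplier = gap_bout_multiplier,
    noncompliant_prob = noncompliant_prob, noise_sd = noise_sd, y = y),
    class = "synth_config")
}

# expected value of the clamped gamma bout duration (deterministic)
mean_bout_duration <- function(cfg) {
  sh <- cfg$bout_duration_shape
  sc <- cfg$bout_duration_scale
  lo <- cfg$bout_duration_min
  hi <- cfg$bout_duration_max
  lo * stats::pgamma(lo, sh, scale = sc) +
    sh * sc * (stats::pgamma(hi, sh + 1, scale = sc) -
                 stats::pgamma(lo, sh + 1, scale = sc)) +
    hi * (1 - stats::pgamma(hi, sh, scale = sc))
}

# one subject-day of HR given a precomputed bout schedule (0-based half-open
# intervals); returns hr vector
synth_day_hr <- function(cfg, rhr, zone_min, bouts, noise) {
  slot <- 0:(MINUTES_PER_DAY - 1L)
  # trough at 04:00; peak in the afternoon
  hr <- rhr + cfg$circadian_amplitude *
    0.5 * (1 - cos(2 * pi * (slot - 240) / MINUTES_PER_DAY))
  if (cfg$noise_sd > 0) hr <- hr + noise
  if (nrow(bouts) > 0L) {
    ramp_frac <- c(0.35, 0.6, 0.85)
    for (k in seq_len(nrow(bouts))) {
      s <- bouts$start[k] + 1L  # R index of first bout minute
      e <- bouts$end[k]         # R index of last bout minute (half-open end)
      plateau <- zone_min + cfg$bout_intensity
      hr[s:e] <- plateau + if (cfg$noise_sd > 0) {
        stats::rnorm(e - s + 1L, 0, cfg$noise_sd)
      } else 0
      if (cfg$bout_ramp > 0L) {
        nr <- cfg$bout_ramp
        fr <- ramp_frac[seq_len(min(nr, length(ramp_frac)))]
        if (nr > length(fr)) fr <- c(seq(0.1, 0.3, length.out = nr - length(fr)), fr)
        up <- (s - length(fr)):(s - 1L)
        ok <- up >= 1L
        # ramps stay strictly below the zone minimum so detected bouts match
        # the scheduled intervals exactly when noise is off
        hr[up[ok]] <- hr[up[ok]] + fr[ok] * (zone_min - hr[up[ok]])
        down <- (e + 1L):(e + length(fr))
        ok <- down <= MINUTES_PER_DAY
        hr[down[ok]] <- hr[down[ok]] + rev(fr)[ok] * (zone_min - hr[down[ok]])
      }
    }
  }
  pmin(pmax(hr, HR_MIN), HR_MAX)
}

# schedule non-overlapping bouts in the 07:00-22:00 window; 0-based
# half-open [start, end) intervals, duration = end - start
schedule_bouts <- function(n, durations, margin) {
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  lo <- 420L
  hi <- 1320L
  starts <- integer(0)
  ends <- integer(0)
  for (d in durations) {
    placed <- FALSE
    for (try in 1:40) {
      s <- sample(lo:(hi - d), 1L)
      e <- s + d
      if (!any(s < ends + margin & e > starts - margin)) {
        starts <- c(starts, s)
        ends <- c(ends, e)
        placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}

# sample dropout gaps for one day; returns logical deletion mask
sample_gaps <- function(cfg, bout_mask, budget = 280L) {
  n_g <- stats::rpois(1L, cfg$gap_rate)
  del <- rep(FALSE, MINUTES_PER_DAY)
  if (n_g == 0L) return(del)
  w <- rep(1, MINUTES_PER_DAY)
  w[bout_mask] <- cfg$gap_bout_multiplier
  lens <- sample(2:150, n_g, replace = TRUE, prob = cfg$gap_len_prob)
  for (L in lens) {
    for (try in 1:20) {
      s <- sample.int(MINUTES_PER_DAY, 1L, prob = w)
      e <- s + L - 1L
      if (e > MINUTES_PER_DAY) next
      idx <- s:e
      # keep gaps separated by at least one present minute so observed
      # missing-run lengths reflect the sampled lengths
      lo <- max(1L, s - 1L)
      hi <- min(MINUTES_PER_DAY, e + 1L)
      if (any(del[lo:hi])) next
      if (sum(del) + L > budget) break
      del[idx] <- TRUE
      break
    }
  }
  del
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces minute-level HR days for every subject and observed calendar
#' date, plus the ground truth needed to score every pipeline stage: the
#' subject table (age, resting HR, true zone minimum, drift, injected
#' label), per-day true target minutes and noncompliance flags, the
#' scheduled bout intervals, and the applied dropout gaps. Missingness is
#' applied last; ground truth is recorded pre-missingness. Reproducible
#' given the config seed and independent of subject ordering.
#'
#' @param cfg a [synth_config()].
#' @return a list with `days` (list of [minute_series()]) and `truth`
#'   (list of data frames `subjects`, `daily`, `bouts`, `gaps`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  cal <- cfg$calendar
  dates <- calendar_dates(cal)
  mi <- month_index(dates, cal)
  phase <- ((mi - 1L) %% cal$period) + 1L
  mean_dur <- mean_bout_duration(cfg)
  margin <- 2L * cfg$bout_ramp + 3L
  all_days <- vector("list", cfg$n_subjects)
  subj_rows <- vector("list", cfg$n_subjects)
  daily_rows <- vector("list", cfg$n_subjects)
  bout_rows <- vector("list", cfg$n_subjects)
  gap_rows <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%03d", i)
    res <- with_seed(stable_hash(paste0("subject-", i), cfg$seed), {
      age <- sample(cfg$age_range[1L]:cfg$age_range[2L], 1L)
      rhr <- max(HR_MIN + 5, stats::rnorm(1L, cfg$rhr_mean, cfg$rhr_sd))
      max_hr <- 220 - age
      zone_min <- karvonen_zone(rhr, max_hr, cfg$y)$zone_min
      drift <- cfg$drift[i]
      m_expect <- pmax(0, cfg$base_target_minutes + drift * (mi - 1L) +
                         cfg$seasonal_profile[phase])
      nd <- length(dates)
      days_i <- vector("list", nd)
      d_target <- integer(nd)
      d_nbouts <- integer(nd)
      d_noncompliant <- logical(nd)
      d_deleted <- integer(nd)
      b_start <- vector("list", nd)
      b_end <- vector("list", nd)
      g_start <- vector("list", nd)
      g_len <- vector("list", nd)
      g_bout <- vector("list", nd)
      for (j in seq_along(dates)) {
        n_b <- stats::rpois(1L, m_expect[j] / mean_dur)
        durs <- if (n_b > 0L) {
          as.integer(pmin(pmax(round(stats::rgamma(n_b, cfg$bout_duration_shape,
                                                   scale = cfg$bout_duration_scale)),
                               cfg$bout_duration_min), cfg$bout_duration_max))
        } else integer(0)
        bouts <- schedule_bouts(n_b, durs, margin)
        noise <- if (cfg$noise_sd > 0) {
          stats::rnorm(MINUTES_PER_DAY, 0, cfg$noise_sd)
        } else numeric(MINUTES_PER_DAY)
        hr <- synth_day_hr(cfg, rhr, zone_min, bouts, noise)
        bout_mask <- rep(FALSE, MINUTES_PER_DAY)
        for (k in seq_len(nrow(bouts))) {
          bout_mask[(bouts$start[k] + 1L):bouts$end[k]] <- TRUE
        }
        noncompliant <- stats::runif(1L) < cfg$noncompliant_prob
        del <- if (cfg$gaps) sample_gaps(cfg, bout_mask) else
          rep(FALSE, MINUTES_PER_DAY)
        if (noncompliant) {
          # one long off-wrist block leaves the day below the 80% threshold
          wear_target <- sample(300:1000, 1L)
          L <- MINUTES_PER_DAY - wear_target
          s <- sample.int(MINUTES_PER_DAY - L + 1L, 1L)
          del[s:(s + L - 1L)] <- TRUE
        }
        hr_obs <- hr
        hr_obs[del] <- NA_real_
        days_i[[j]] <- minute_series(sid, dates[j], hr_obs)
        d_target[j] <- sum(bouts$end - bouts$start)
        d_nbouts[j] <- nrow(bouts)
        d_noncompliant[j] <- noncompliant
        d_deleted[j] <- sum(del)
        if (nrow(bouts) > 0L) {
          b_start[[j]] <- bouts$start  # 0-based half-open
          b_end[[j]] <- bouts$end
        }
        if (any(del)) {
          r <- rle(del)
          e2 <- cumsum(r$lengths)
          s2 <- e2 - r$lengths + 1L
          g_start[[j]] <- s2[r$values] - 1L
          g_len[[j]] <- r$lengths[r$values]
          g_bout[[j]] <- vapply(which(r$values), function(q)
            any(bout_mask[s2[q]:e2[q]]), TRUE)
        }
      }
      nb_per_day <- vapply(b_start, length, 0L)
      ng_per_day <- vapply(g_start, length, 0L)
      bouts_df <- if (sum(nb_per_day) > 0L) {
        st <- unlist(b_start)
        en <- unlist(b_end)
        data.frame(subject_id = sid, date = rep(dates, nb_per_day),
                   start = st, end = en, duration = en - st,
                   stringsAsFactors = FALSE)
      } else NULL
      gaps_df <- if (sum(ng_per_day) > 0L) {
        data.frame(subject_id = sid, date = rep(dates, ng_per_day),
                   start = unlist(g_start), length = unlist(g_len),
                   during_bout = unlist(g_bout), stringsAsFactors = FALSE)
      } else NULL
      list(days = days_i,
           subject = data.frame(
             subject_id = sid, age = age, rhr = rhr, max_hr = max_hr,
             zone_min = zone_min, drift = drift,
             label = if (drift > 0) "positive" else if (drift < 0)
               "negative" else "none",
             stringsAsFactors = FALSE),
           daily = data.frame(
             subject_id = sid, date = dates, month = cal$months[mi],
             true_target_minutes = d_target, n_bouts = d_nbouts,
             noncompliant = d_noncompliant, deleted_minutes = d_deleted,
             stringsAsFactors = FALSE),
           bouts = bouts_df,
           gaps = gaps_df)
    })
    all_days[[i]] <- res$days
    subj_rows[[i]] <- res$subject
    daily_rows[[i]] <- res$daily
    bout_rows[[i]] <- res$bouts
    gap_rows[[i]] <- res$gaps
  }
  empty_gaps <- data.frame(subject_id = character(), date = as.Date(character()),
                           start = integer(), length = integer(),
                           during_bout = logical())
  list(days = do.call(c, all_days),
       truth = list(subjects = do.call(rbind, subj_rows),
                    daily = do.call(rbind, daily_rows),
                    bouts = do.call(rbind, bout_rows),
                    gaps = if (is.null(gr <- do.call(rbind, gap_rows)))
                      empty_gaps else gr))
}

#' Generate gap-free synthetic days for the imputation benchmark
#'
#' Complete 24-hour records (no gaps, no noncompliance) with the configured
#' circadian baseline, bouts and noise; deterministic given the config seed
#' and independent of `n`-ordering (day k is the same whatever `n` is).
#'
#' @param n number of days.
#' @param cfg a [synth_config()].
#' @return list of `n` complete [minute_series()].
#' @export
generate_complete_days <- function(n, cfg) {
  stopifnot(inherits(cfg, "synth_config"), n >= 0L)
  if (n == 0L) return(list())
  dates <- calendar_dates(cfg$calendar)
  mean_dur <- mean_bout_duration(cfg)
  margin <- 2L * cfg$bout_ramp + 3L
  lapply(seq_len(n), function(k) {
    with_seed(stable_hash(paste0("complete-", k), cfg$seed), {
      rhr <- max(HR_MIN + 5, stats::rnorm(1L, cfg$rhr_mean, cfg$rhr_sd))
      age <- sample(cfg$age_range[1L]:cfg$age_range[2L], 1L)
      zone_min <- karvonen_zone(rhr, 220 - age, cfg$y)$zone_min
      n_b <- stats::rpois(1L, cfg$base_target_minutes / mean_dur)
      durs <- if (n_b > 0L) {
        as.integer(pmin(pmax(round(stats::rgamma(n_b, cfg$bout_duration_shape,
                                                 scale = cfg$bout_duration_scale)),
                             cfg$bout_duration_min), cfg$bout_duration_max))
      } else integer(0)
      bouts <- schedule_bouts(n_b, durs, margin)
      noise <- if (cfg$noise_sd > 0) {
        stats::rnorm(MINUTES_PER_DAY, 0, cfg$noise_sd)
      } else numeric(MINUTES_PER_DAY)
      minute_series(sprintf("C%04d", k),
                    dates[((k - 1L) %% length(dates)) + 1L],
                    synth_day_hr(cfg, rhr, zone_min, bouts, noise))
    })
  })
}
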