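#' Imputation configuration
#'
#' @param max_gap_minutes longest missing run eligible for imputation
#'   (default 150 min, the longest gap length commonly observed in wearable
#'   HR records).
#' @param missing_target_fraction fraction of the day deleted by the
#'   block-deletion benchmark (default 0.20).
#' @param block_lengths block lengths (minutes) exercised by the benchmark
#'   (default 25, 50, 150).
#' @return a list of class `imputation_config`.
#' @export
imputation_config <- function(max_gap_minutes = 150L,
                              missing_target_fraction = 0.20,
                              block_lengths = c(25L, 50L, 150L)) {
  max_gap_minutes <- as.integer(max_gap_minutes)
  stopifnot(max_gap_minutes >= 1L,
            missing_target_fraction > 0, missing_target_fraction < 1,
            all(block_lengths >= 1L))
  structure(list(max_gap_minutes = max_gap_minutes,
                 missing_target_fraction = missing_target_fraction,
                 block_lengths = as.integer(block_lengths)),
            class = "imputation_config")
}

#' Impute within-day heart-rate gaps by linear interpolation
#'
#' Every interior missing run of length at most `max_gap_minutes` is filled
#' by straight-line interpolation between the flanking present values.
#' Leading/trailing runs (no flank on one side) and runs longer than the cap
#' are left missing; present values are never altered. A day with fewer than
#' two present minutes is returned unchanged. Imputed values are real-valued
#' (downstream zone comparison is threshold-based; rounding would bias it).
#'
#' @param day a [minute_series()].
#' @param max_gap_minutes longest gap to fill (default 150).
#' @return a [minute_series()] with attribute `imputed`: logical mask of the
#'   filled slots.
#' @export
impute_linear <- function(day, max_gap_minutes = 150L) {
  stopifnot(inherits(day, "minute_series"))
  hr <- day$hr
  if (sum(!is.na(hr)) < 2L || !anyNA(hr)) {
    out <- day
    attr(out, "imputed") <- rep(FALSE, MINUTES_PER_DAY)
    return(out)
  }
  pres <- which(!is.na(hr))
  miss <- which(is.na(hr))
  miss <- miss[miss > pres[1L] & miss < pres[length(pres)]]  # interior only
  filled <- hr
  if (length(miss) > 0L) {
    li <- findInterval(miss, pres)       # index of left flanking present slot
    l <- pres[li]
    r <- pres[li + 1L]
    ok <- (r - l - 1L) <= max_gap_minutes  # gap length cap
    l <- l[ok]
    r <- r[ok]
    m <- miss[ok]
    filled[m] <- hr[l] + (m - l) / (r - l) * (hr[r] - hr[l])
  }
  out <- minute_series(day$subject_id, day$date, filled)
  attr(out, "imputed") <- is.na(hr) & !is.na(filled)
  out
}

#' Delete random non-overlapping blocks from a complete day
#'
#' Removes contiguous blocks of exactly `block_length` minutes, chosen
#' uniformly at random among feasible (non-overlapping; touching allowed)
#' positions without replacement, until the deleted fraction first reaches
#' `target_fraction` — the last block may overshoot. Deterministic given
#' `seed`.
#'
#' @param day a complete [minute_series()] (no missing minutes).
#' @param block_length block size in minutes (at most 1440).
#' @param target_fraction fraction of the day to delete (default 0.20).
#' @param seed integer RNG seed.
#' @return a list with `day` (the degraded [minute_series()]) and `mask`
#'   (logical vector marking deleted slots).
#' @export
delete_blocks <- function(day, block_length, target_fraction = 0.20,
                          seed = 1L) {
  stopifnot(inherits(day, "minute_series"))
  if (anyNA(day$hr)) stopf("delete_blocks requires a complete day")
  block_length <- as.integer(block_length)
  if (block_length < 1L || block_length > MINUTES_PER_DAY) {
    stopf("block_length must be in [1, %d]", MINUTES_PER_DAY)
  }
  stopifnot(target_fraction >= 0, target_fraction < 1)
  deleted <- rep(FALSE, MINUTES_PER_DAY)
  need <- target_fraction * MINUTES_PER_DAY
  with_seed(seed, {
    while (sum(deleted) < need) {
      cs <- c(0L, cumsum(deleted))
      starts <- which(cs[(block_length + 1L):(MINUTES_PER_DAY + 1L)] -
                        cs[1L:(MINUTES_PER_DAY - block_length + 1L)] == 0L)
      if (length(starts) == 0L) {
        warnf("no feasible block position left before reaching target fraction")
        break
      }
      s <- starts[sample.int(length(starts), 1L)]
      deleted[s:(s + block_length - 1L)] <- TRUE
    }
  })
  hr <- day$hr
  hr[deleted] <- NA_real_
  list(day = minute_series(day$subject_id, day$date, hr), mask = deleted)
}

#' Root-mean-square error of imputed values over a deletion mask
#'
#' @param original the complete [minute_series()].
#' @param imputed the imputed [minute_series()].
#' @param mask logical vector of the deleted slots to score.
#' @return RMSE in beats/min.
#' @export
imputation_rmse <- function(original, imputed, mask) {
  stopifnot(inherits(original, "minute_series"),
            inherits(imputed, "minute_series"),
            length(mask) == MINUTES_PER_DAY)
  if (!any(mask)) stopf("empty deletion mask")
  err <- imputed$hr[mask] - original$hr[mask]
  if (anyNA(err)) stopf("mask contains slots the imputer left missing")
  sqrt(mean(err^2))
}

#' Block-deletion imputation benchmark
#'
#' The protocol that justifies an imputation method: complete 24-hour records
#' are degraded by random block deletion ([delete_blocks()]) at each
#' configured block length, each candidate method re-imputes them, and the
#' squared errors on deleted slots are pooled into one RMSE per
#' method × block length. Per-day RNG substreams are derived from the day's
#' identity, so results are reproducible given `seed` and invariant to day
#' ordering.
#'
#' @param complete_days list of complete [minute_series()].
#' @param methods named list of imputers `function(day, cfg) -> minute_series`;
#'   the default entry is capped linear interpolation. Further methods (e.g.
#'   Kalman-smoother models) plug in through the same contract.
#' @param cfg an [imputation_config()].
#' @param seed integer base seed.
#' @return data frame with columns `method`, `block_length`, `rmse`.
#' @export
benchmark_imputation <- function(complete_days,
                                 methods = list(
                                   linear = function(day, cfg)
                                     impute_linear(day, cfg$max_gap_minutes)),
                                 cfg = imputation_config(), seed = 1L) {
  if (length(complete_days) == 0L) stopf("no complete days supplied")
  for (d in complete_days) {
    if (anyNA(d$hr)) {
      stopf("day %s/%s is not complete", d$subject_id, format(d$date))
    }
  }
  stopifnot(!is.null(names(methods)), all(nzchar(names(methods))))
  res <- list()
  for (L in cfg$block_lengths) {
    # one degradation per day, shared across methods
    degraded <- lapply(complete_days, function(d) {
      dseed <- stable_hash(paste("bench", d$subject_id, format(d$date), L),
                           seed)
      delete_blocks(d, L, cfg$missing_target_fraction, seed = dseed)
    })
    for (m in names(methods)) {
      se <- 0
      n <- 0L
      for (i in seq_along(complete_days)) {
        imp <- methods[[m]](degraded[[i]]$day, cfg)
        err <- imp$hr[degraded[[i]]$mask] - complete_days[[i]]$hr[degraded[[i]]$mask]
        err <- err[!is.na(err)]  # slots a capped imputer left missing are skipped
        se <- se + sum(err^2)
        n <- n + length(err)
      }
      res[[length(res) + 1L]] <- data.frame(
        method = m, block_length = L,
        rmse = if (n > 0L) sqrt(se / n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out[order(out$block_length, out$method), , drop = FALSE]
}
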