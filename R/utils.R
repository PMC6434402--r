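#' @keywords internal
"_PACKAGE"

MINUTES_PER_DAY <- 1440L
HR_MIN <- 25
HR_MAX <- 250

#' Stable 31-bit hash of a character key mixed with a base seed
#'
#' Used to derive independent RNG substreams (per subject, per benchmark day)
#' from a single global seed, so that generated data do not depend on the
#' order in which subjects or days are processed. Polynomial rolling hash
#' modulo the Mersenne prime 2^31 - 1; exact in double precision.
#'
#' @param key character scalar.
#' @param seed integer base seed.
#' @return an integer in [1, 2^31 - 2], usable with [set.seed()].
#' @keywords internal
stable_hash <- function(key, seed) {
  p <- 2147483647
  h <- (seed %% p)
  for (v in utf8ToInt(key)) {
    h <- (h * 31 + v) %% p
  }
  as.integer(h %% (p - 2) + 1)
}

#' Run code with a temporary RNG seed, restoring global RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# half-open [start, end) date-interval membership
date_in_ranges <- function(dates, ranges) {
  if (is.null(ranges) || nrow(ranges) == 0L) return(rep(FALSE, length(dates)))
  out <- rep(FALSE, length(dates))
  for (i in seq_len(nrow(ranges))) {
    out <- out | (dates >= ranges$start[i] & dates < ranges$end[i])
  }
  out
}

month_key <- function(dates) format(dates, "%Y-%m")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
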