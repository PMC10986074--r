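#' Construct a uniformly sampled count series
#'
#' A \code{count_series} holds a nonnegative, uniformly sampled sequence of
#' activity counts (or any physiological count signal) together with its
#' start time and sampling interval. Minute-epoch actigraphy counts are the
#' canonical input: one value per minute, recording start at an arbitrary
#' clock time.
#'
#' @param values numeric vector of nonnegative counts, length >= 2. Stored as
#'   doubles; pre-scaled (non-integer) counts are accepted.
#' @param start_time POSIXct timestamp of the first sample. Defaults to
#'   1970-01-01 00:00 UTC, which is adequate whenever only relative time
#'   matters.
#' @param dt_sec sampling interval in seconds (constant across the series).
#'   Default 60 (minute epochs).
#' @return an object of class \code{count_series}: the numeric vector with
#'   attributes \code{start_time} and \code{dt_sec}.
#' @examples
#' x <- count_series(rpois(1440, 100))
#' x
#' @export
count_series <- function(values,
                         start_time = as.POSIXct("1970-01-01", tz = "UTC"),
                         dt_sec = 60) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("count series too short: need at least 2 samples, got ",
         length(values))
  if (anyNA(values))
    stop("count series contains missing values")
  if (any(values < 0))
    stop("negative counts at position(s) ",
         paste(utils::head(which(values < 0), 5L), collapse = ", "))
  if (!is.numeric(dt_sec) || length(dt_sec) != 1L || !is.finite(dt_sec) ||
      dt_sec <= 0)
    stop("dt_sec must be a single positive number")
  if (!inherits(start_time, "POSIXct")) {
    start_time <- as.POSIXct(start_time, tz = "UTC")
    if (is.na(start_time)) stop("start_time could not be parsed")
  }
  structure(values, start_time = start_time, dt_sec = as.numeric(dt_sec),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %d samples @ %gs (%.2f days), start %s\n",
              length(x), dt_sec(x), length(x) * dt_sec(x) / 86400,
              format(start_time(x), "%Y-%m-%d %H:%M %Z")))
  cat(sprintf("  mean %.3f, range [%g, %g]\n",
              mean(unclass(x)), min(x), max(x)))
  invisible(x)
}

#' @export
as.data.frame.count_series <- function(x, ...) {
  data.frame(timestamp = start_time(x) + (seq_along(x) - 1L) * dt_sec(x),
             counts = as.numeric(x))
}

#' @rdname count_series
#' @param x a \code{count_series}
#' @export
start_time <- function(x) attr(x, "start_time")

#' @rdname count_series
#' @export
dt_sec <- function(x) attr(x, "dt_sec")

#' Number of samples that make up one day
#' @param x a \code{count_series}
#' @return integer samples per 24 h (1440 at minute sampling)
#' @export
samples_per_day <- function(x) {
  spd <- 86400 / dt_sec(x)
  if (abs(spd - round(spd)) > 1e-9)
    stop("sampling interval does not divide a day evenly")
  as.integer(round(spd))
}

#' Validate a count series
#'
#' Checks the hard invariants (nonnegative values, length >= 2, positive
#' sampling interval) and, optionally, screens for possible non-wear time:
#' any 24 h block with more than \code{zero_frac} of its samples exactly zero
#' raises a warning (never an error), since extended runs of zeros in wrist
#' actigraphy usually mean the device was off rather than the subject
#' motionless. Sleep alone also produces zeros, so the check is a prompt for
#' manual review, not a rejection rule.
#'
#' @param series a \code{count_series}
#' @param warn_nonwear logical; run the zero-fraction screen (default TRUE)
#' @param zero_frac warning threshold on the per-day fraction of exact zeros
#'   (default 0.05)
#' @return the series, unchanged, invisibly-checkable in pipelines
#' @export
validate_count_series <- function(series, warn_nonwear = TRUE,
                                  zero_frac = 0.05) {
  if (!inherits(series, "count_series"))
    stop("not a count_series")
  v <- as.numeric(series)
  if (length(v) < 2L) stop("count series too short")
  if (any(v < 0)) stop("negative counts")
  if (dt_sec(series) <= 0) stop("non-positive sampling interval")
  if (warn_nonwear) {
    spd <- samples_per_day(series)
    nfull <- length(v) %/% spd
    if (nfull >= 1L) {
      day <- rep(seq_len(nfull), each = spd)
      zf <- tapply(v[seq_len(nfull * spd)] == 0, day, mean)
      bad <- which(zf > zero_frac)
      if (length(bad))
        warning(sprintf(
          "possible non-wear: > %.0f%% zero counts on day(s) %s (max %.0f%%)",
          100 * zero_frac, paste(utils::head(bad, 10L), collapse = ", "),
          100 * max(zf)), call. = FALSE)
    }
  }
  series
}

#' Extract whole recording days from a count series
#'
#' Days are indexed by sample position from the recording start: day k covers
#' samples ((k-1)*spd + 1) .. (k*spd), where spd is \code{\link{samples_per_day}}
#' (1440 at minute sampling). This follows recording days, not wall-clock
#' midnights, because recordings start at arbitrary clock times.
#'
#' @param series a \code{count_series}
#' @param first_day,last_day 1-based day indices, inclusive,
#'   \code{first_day <= last_day}
#' @param allow_short_tail if the recording ends before \code{last_day}, warn
#'   and truncate to the last complete-or-partial available day (default)
#'   instead of raising an error
#' @return the contiguous sub-series, with its start time advanced accordingly
#' @examples
#' x <- gen_iid(days = 21, seed = 1)
#' wk1 <- slice_days(x, 1, 7)
#' @export
slice_days <- function(series, first_day, last_day,
                       allow_short_tail = TRUE) {
  stopifnot(inherits(series, "count_series"))
  first_day <- as.integer(first_day); last_day <- as.integer(last_day)
  if (first_day < 1L || last_day < first_day)
    stop("invalid day span: need 1 <= first_day <= last_day")
  spd <- samples_per_day(series)
  from <- (first_day - 1L) * spd + 1L
  to <- last_day * spd
  n <- length(series)
  if (from > n)
    stop("day span starts beyond the end of the recording")
  if (to > n) {
    if (!allow_short_tail)
      stop("day span extends beyond the recording (", n %/% spd,
           " full days available)")
    warning(sprintf("recording ends inside day %d; truncating span to %d samples",
                    last_day, n - from + 1L), call. = FALSE)
    to <- n
  }
  count_series(as.numeric(series)[from:to],
               start_time = start_time(series) + (from - 1L) * dt_sec(series),
               dt_sec = dt_sec(series))
}

#' Total number of (possibly partial) recording days
#' @param series a \code{count_series}
#' @return number of days covered, as a real number
#' @export
n_days <- function(series) length(series) / samples_per_day(series)
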