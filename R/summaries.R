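#' Week spans for a 3-week recording
#'
#' Weeks are indexed by recording day: days 1-7, 8-14 and 15 to the end. The
#' non-overlapping split is the default; \code{week3_from_day14 = TRUE}
#' starts the third week at day 14 instead, for reproduction of analyses
#' that count day 14 into both week 2 and week 3.
#'
#' @param total_days number of (possibly partial) days in the recording
#' @param week3_from_day14 include day 14 in week 3 (default FALSE)
#' @return data.frame: \code{week, first_day, last_day}
#' @export
week_spans <- function(total_days, week3_from_day14 = FALSE) {
  total_days <- as.integer(floor(total_days))
  if (total_days < 15L) stop("need at least 15 recording days for 3 weeks")
  data.frame(week = 1:3,
             first_day = c(1L, 8L, if (week3_from_day14) 14L else 15L),
             last_day = c(7L, 14L, total_days))
}

#' Daily activity-count sums
#'
#' @param series a \code{count_series}
#' @return numeric vector: total counts per complete 1440-sample day (a
#'   trailing partial day is dropped)
#' @export
daily_sums <- function(series) {
  stopifnot(inherits(series, "count_series"))
  spd <- samples_per_day(series)
  nfull <- length(series) %/% spd
  if (nfull < 1L) stop("series shorter than one day")
  v <- as.numeric(series)[seq_len(nfull * spd)]
  as.numeric(tapply(v, rep(seq_len(nfull), each = spd), sum))
}

#' Weekly static summaries of a 3-week recording
#'
#' For each week the adapted allometric aggregation is run independently on
#' that week's slice and the scale-local fractal dimension is evaluated at
#' \code{eval_scale}; daily activity statistics (mean and sd of the daily
#' count sums, total counts) are reported alongside. The default parameters
#' (n_min = 1, n_max = 540 = 9 h, s = 1.1, evaluation at 180 = 3 h) are the
#' configuration used for weekly tables on 3-week minute-resolution
#' recordings.
#'
#' @param series a \code{count_series} spanning at least 20 days
#' @param n_min,n_max,s,overlap AAA parameters
#' @param eval_scale evaluation level in samples (default 180 = 3 h)
#' @param week3_from_day14 see \code{\link{week_spans}}
#' @return data.frame of class \code{week_summary}: \code{week, first_day,
#'   last_day, fd, slope_b, total_counts, daily_mean, daily_sd}
#' @export
weekly_summaries <- function(series, n_min = 1, n_max = 540, s = 1.1,
                             overlap = 0.5, eval_scale = 180,
                             week3_from_day14 = FALSE) {
  stopifnot(inherits(series, "count_series"))
  if (n_days(series) < 20)
    stop("weekly summaries expect a recording of at least 20 days")
  spans <- week_spans(n_days(series), week3_from_day14)
  rows <- lapply(seq_len(nrow(spans)), function(i) {
    wk <- slice_days(series, spans$first_day[i], spans$last_day[i])
    fit <- aaa(wk, n_min, n_max, s, overlap)
    est <- local_fd(fit, eval_scale, dt_sec = dt_sec(series))
    ds <- daily_sums(wk)
    data.frame(week = spans$week[i], first_day = spans$first_day[i],
               last_day = spans$last_day[i],
               fd = est$D, slope_b = est$slope_b,
               total_counts = sum(as.numeric(wk)),
               daily_mean = mean(ds), daily_sd = stats::sd(ds))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("week_summary", "data.frame")
  out
}

#' Global static fractal dimension of a full recording
#'
#' One AAA pass over the entire series, evaluated at \code{eval_scale}. On
#' smoothly varying signals this tends to summarise the weekly values but is
#' not their average and need not lie between them.
#'
#' @inheritParams weekly_summaries
#' @return one-row data.frame: \code{n, timescale_min, slope_b, D}
#' @export
global_fd <- function(series, n_min = 1, n_max = 540, s = 1.1,
                      overlap = 0.5, eval_scale = 180) {
  fit <- aaa(series, n_min, n_max, s, overlap)
  local_fd(fit, eval_scale,
           dt_sec = if (inherits(series, "count_series")) dt_sec(series)
                    else 60)
}

#' Correlation between windowed complexity and windowed activity
#'
#' Samples the complexity track a few times a day (every
#' \code{24/samples_per_day} hours, starting at the first available track
#' point) and pairs each sampled fractal dimension with the sum of activity
#' counts inside the same trailing window, then reports the Pearson
#' correlation of the pairs. Pairs whose fractal dimension is missing are
#' dropped; a constant fractal-dimension sample has no defined correlation
#' and yields NA with a warning.
#'
#' @param series the \code{count_series} the track was computed from
#' @param track a \code{\link{run_taaa}} result (single evaluation scale, or
#'   specify \code{scale})
#' @param samples_per_day how many instants per day to sample (default 3,
#'   i.e. every 8 h)
#' @param scale evaluation scale to use when the track holds several
#'   (default: the first)
#' @return list: \code{r} (Pearson correlation), \code{n_pairs}, and the
#'   sampled \code{pairs} data.frame
#' @export
fd_activity_correlation <- function(series, track, samples_per_day = 3,
                                    scale = NULL) {
  stopifnot(inherits(series, "count_series"),
            inherits(track, "complexity_track"))
  if (is.null(scale)) scale <- track$n[1L]
  tr <- track[track$n == scale, , drop = FALSE]
  if (!nrow(tr)) stop("track holds no estimates at scale ", scale)
  spd <- samples_per_day(series)
  every <- spd %/% samples_per_day            # samples between instants
  step <- attr(track, "window")$step
  width <- attr(track, "window")$width
  targets <- seq(tr$end_index[1L], max(tr$end_index), by = every)
  # nearest available window end for each sampling instant
  idx <- findInterval(targets + step / 2, tr$end_index)
  idx <- pmax(idx, 1L)
  sel <- tr[idx, , drop = FALSE]
  off <- abs(sel$end_index - targets)
  keep <- off <= step / 2 & sel$status == "ok" & !is.na(sel$D)
  sel <- sel[keep, , drop = FALSE]
  if (nrow(sel) < 3L) stop("fewer than 3 valid complexity/activity pairs")
  cs <- c(0, cumsum(as.numeric(series)))
  act <- cs[sel$end_index + 1L] - cs[sel$end_index - width + 1L]
  pairs <- data.frame(end_index = sel$end_index, time = sel$time,
                      D = sel$D, activity = act)
  if (stats::sd(pairs$D) == 0 || stats::sd(pairs$activity) == 0) {
    warning("zero variance in sampled complexity or activity; ",
            "correlation undefined", call. = FALSE)
    return(list(r = NA_real_, n_pairs = nrow(pairs), pairs = pairs))
  }
  list(r = stats::cor(pairs$D, pairs$activity), n_pairs = nrow(pairs),
       pairs = pairs)
}

#' Convert functioning labels to ordinal ranks
#'
#' Physicians' weekly labels (\code{"worst"}, \code{"average"},
#' \code{"best"}, or already-numeric ranks 1-3 with 1 = worst) become
#' average-rank ordinals: a partial ranking such as (average, best, average)
#' yields ranks (1.5, 3, 1.5).
#'
#' @param labels character or numeric vector of length 3
#' @return numeric ranks with ties averaged
#' @export
functioning_ranks <- function(labels) {
  if (is.numeric(labels)) {
    val <- labels
  } else {
    val <- match(tolower(trimws(labels)), c("worst", "average", "best"))
    if (anyNA(val))
      stop("labels must be worst/average/best or numeric ranks")
  }
  rank(val)
}

#' Rank correlation between weekly functioning and a weekly metric
#'
#' Spearman rank correlation across the three observation weeks between the
#' physicians' functioning ranking (1 = worst ... 3 = best, ties averaged)
#' and either the complexity ranking (weeks ranked from low complexity =
#' high fractal dimension to high complexity = low fractal dimension, i.e.
#' the inverted fractal-dimension ranking) or the activity ranking (low to
#' high total weekly counts). A positive coefficient therefore means better
#' functioning goes with higher complexity (or more activity). With only 3
#' items the coefficient is heavily quantised: untied rankings give rho in
#' {-1, -0.5, 0.5, 1}; one tied pair gives {-0.866, 0, 0.866}. The p-value
#' uses the t reference distribution with n - 2 degrees of freedom, under
#' which only |rho| = 1 is significant at 3 points (p < 0.001; |rho| = 0.866
#' gives p = 0.33 and |rho| = 0.5 gives p = 0.67).
#'
#' @param ranking functioning ranks or labels (see
#'   \code{\link{functioning_ranks}})
#' @param weekly a \code{\link{weekly_summaries}} result, or a numeric
#'   vector of the weekly metric values
#' @param against "complexity" (rank by inverted fractal dimension) or
#'   "activity" (rank by total weekly counts)
#' @return list: \code{rho}, \code{p_value}, and the two rank vectors
#' @export
functioning_rank_correlation <- function(ranking, weekly,
                                         against = c("complexity",
                                                     "activity")) {
  against <- match.arg(against)
  fr <- functioning_ranks(ranking)
  vals <- if (is.numeric(weekly)) weekly
          else switch(against, complexity = weekly$fd,
                      activity = weekly$total_counts)
  if (length(fr) != length(vals))
    stop("ranking and weekly metric lengths differ")
  mr <- if (against == "complexity") rank(-vals) else rank(vals)
  res <- spearman_small(fr, mr)
  c(res, list(functioning_ranks = fr, metric_ranks = mr, against = against))
}

#' Spearman correlation with t-based p-value for tiny samples
#'
#' Pearson correlation of average ranks, with a two-sided p-value from the
#' t distribution on n - 2 degrees of freedom (\code{t = rho * sqrt((n - 2) /
#' (1 - rho^2))}; a perfect correlation gives p = 0). On 3 items this
#' reference distribution is the one under which only |rho| = 1 is reported
#' significant.
#'
#' @param a,b numeric vectors (ranks or raw values; ranked internally with
#'   ties averaged)
#' @return list: \code{rho}, \code{p_value}
#' @export
spearman_small <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  n <- length(ra)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    return(list(rho = NA_real_, p_value = NA_real_))
  rho <- stats::cor(ra, rb)
  p <- if (abs(rho) >= 1) 0
       else 2 * stats::pt(-abs(rho) * sqrt((n - 2) / (1 - rho^2)), n - 2)
  list(rho = rho, p_value = p)
}
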