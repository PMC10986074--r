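#' Sliding-window specification for temporal complexity analysis
#'
#' A trailing window of \code{width} samples advances in steps of \code{step}
#' samples; each position summarises the immediately preceding
#' \code{width}-long stretch of the series. The window must be comfortably
#' larger than the largest aggregation scale analysed inside it: with fewer
#' than 8 window-widths per \code{n_max} the variance at the top scales is
#' estimated from very few segments (a warning), and below 2 widths the
#' estimate is meaningless (an error).
#'
#' @param width window width in samples (default 4320 = 72 h at minute
#'   sampling)
#' @param step advance between successive windows in samples (default 5)
#' @param n_max largest aggregation level that will be used inside the
#'   window, for the reliability guard; NULL skips the guard
#' @return a list of class \code{window_spec}
#' @export
window_spec <- function(width = 4320, step = 5, n_max = NULL) {
  width <- as.integer(width); step <- as.integer(step)
  if (width < 2L) stop("window width must be >= 2 samples")
  if (step < 1L || step > width)
    stop("step must satisfy 1 <= step <= width")
  if (!is.null(n_max)) {
    if (width < 2L * n_max)
      stop("window width ", width, " is below 2 x n_max = ", 2L * n_max,
           "; the window must be at least twice the maximum aggregation scale")
    if (width < 8L * n_max)
      warning("window width ", width, " is below the recommended 8 x n_max = ",
              8L * n_max, "; top-scale variance estimates may be unreliable",
              call. = FALSE)
  }
  structure(list(width = width, step = step), class = "window_spec")
}

#' Temporal adapted allometric aggregation (t-AAA)
#'
#' Slides a trailing window along the series and runs the adapted allometric
#' aggregation inside every window, producing a time-indexed (and
#' scale-indexed) fractal-dimension track: each track point, stamped with the
#' window-end time, is the fractal dimension of the stretch of signal that
#' just ended. Windows whose fit fails (e.g. windows of all-zero counts)
#' yield missing values, never an abort, so the track length formula
#' \code{floor((N - width)/step) + 1} stays exact.
#'
#' @param series a \code{count_series}
#' @param window a \code{\link{window_spec}}; its reliability guard is applied
#'   against \code{n_max}
#' @param n_min,n_max,s,overlap AAA parameters applied inside each window
#'   (defaults: study configuration n_min = 1, n_max = 540 = 9 h, s = 1.1)
#' @param eval_scales aggregation levels at which the local fractal dimension
#'   is evaluated in every window (default 180 = 3 h at minute sampling)
#' @return data.frame of class \code{complexity_track}, long format, one row
#'   per window per evaluation scale: \code{time, end_index, n,
#'   timescale_min, slope_b, D, n_levels, status}. Failed windows carry
#'   \code{status = "failed"} and NA estimates.
#' @examples
#' x <- gen_iid(days = 7, seed = 1)
#' tr <- run_taaa(x, window_spec(width = 4320, step = 720), n_max = 256)
#' @export
run_taaa <- function(series, window = window_spec(), n_min = 1, n_max = 540,
                     s = 1.1, overlap = 0.5, eval_scales = 180) {
  stopifnot(inherits(series, "count_series"))
  if (!inherits(window, "window_spec"))
    stop("window must be a window_spec")
  # re-apply the guard with the actual schedule in force
  window_spec(window$width, window$step, n_max = n_max)
  v <- as.numeric(series)
  N <- length(v)
  if (N < window$width)
    stop("series (", N, " samples) shorter than one window (",
         window$width, ")")
  sched <- build_schedule(n_min, n_max, s)
  starts <- seq.int(1L, N - window$width + 1L, by = window$step)
  ends <- starts + window$width - 1L
  dts <- dt_sec(series)
  times <- start_time(series) + ends * dts
  rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    sub <- v[starts[i]:ends[i]]
    est <- tryCatch({
      curve <- suppressWarnings(compute_curve(sub, sched, overlap = overlap))
      fit <- fit_loglog(curve)
      cbind(do.call(rbind, lapply(eval_scales, function(n)
        local_fd(fit, n, dt_sec = dts))),
        n_levels = length(fit$levels), status = "ok")
    }, error = function(e) {
      data.frame(n = eval_scales, timescale_min = eval_scales * dts / 60,
                 slope_b = NA_real_, D = NA_real_,
                 n_levels = 0L, status = "failed")
    })
    est$time <- times[i]
    est$end_index <- ends[i]
    rows[[i]] <- est
  }
  out <- do.call(rbind, rows)
  out <- out[, c("time", "end_index", "n", "timescale_min", "slope_b", "D",
                 "n_levels", "status")]
  rownames(out) <- NULL
  structure(out,
            class = c("complexity_track", "data.frame"),
            window = window, schedule = sched,
            series_start = start_time(series), dt_sec = dts,
            series_length = N)
}

#' @export
print.complexity_track <- function(x, ...) {
  w <- attr(x, "window")
  nw <- length(unique(x$end_index))
  cat(sprintf(
    "<complexity_track> %d windows (width %d, step %d), scales: %s\n",
    nw, w$width, w$step, paste(unique(x$n), collapse = ", ")))
  ok <- x$status == "ok"
  cat(sprintf("  %d/%d window-scale points ok; D range [%.3f, %.3f]\n",
              sum(ok), nrow(x),
              suppressWarnings(min(x$D[ok])),
              suppressWarnings(max(x$D[ok]))))
  invisible(x)
}

#' Per-period descriptive statistics of a complexity track
#'
#' Splits the track into consecutive periods of \code{period} samples
#' (anchored at the recording start; a window belongs to the period its end
#' falls in) and reports the mean, min and max fractal dimension per period
#' and evaluation scale. Note: the temporal mean of windowed fractal
#' dimensions is \emph{not} the same quantity as the static fractal dimension
#' of the whole period computed in one pass — aggregating-then-averaging and
#' averaging-then-aggregating answer different questions, and on structured
#' signals the two differ.
#'
#' @param track a \code{\link{run_taaa}} result
#' @param period period length in samples (default 10080 = one week at minute
#'   sampling); must be >= the track step
#' @return data.frame: \code{period, n, n_windows, mean_D, min_D, max_D};
#'   periods containing no window ends yield NA statistics
#' @export
summarize_track <- function(track, period = 10080) {
  stopifnot(inherits(track, "complexity_track"))
  period <- as.integer(period)
  if (period < attr(track, "window")$step)
    stop("period must be at least one track step")
  n_per <- ceiling(attr(track, "series_length") / period)
  pid <- (track$end_index - 1L) %/% period + 1L
  out <- expand.grid(period = seq_len(n_per), n = unique(track$n),
                     KEEP.OUT.ATTRS = FALSE)
  stat <- function(p, n) {
    d <- track$D[pid == p & track$n == n & track$status == "ok"]
    if (!length(d)) return(c(0L, NA_real_, NA_real_, NA_real_))
    c(length(d), mean(d), min(d), max(d))
  }
  m <- t(mapply(stat, out$period, out$n))
  out$n_windows <- as.integer(m[, 1L])
  out$mean_D <- m[, 2L]; out$min_D <- m[, 3L]; out$max_D <- m[, 4L]
  out
}
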