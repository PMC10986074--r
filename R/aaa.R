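round_half_up <- function(x) floor(x + 0.5)

#' Geometric schedule of aggregation levels
#'
#' Block sizes for the adapted allometric aggregation method are spread
#' evenly in log space rather than incremented by 1: each level is the
#' previous one multiplied by a constant factor \code{s > 1}, rounded half-up,
#' with a +1 guard that forces progress when rounding would stall (so any
#' \code{s > 1} terminates and the levels are strictly increasing).
#' \code{n_max} is appended if the recurrence does not land on it.
#'
#' @param n_min smallest block size (>= 1)
#' @param n_max largest block size (> n_min)
#' @param s multiplicative scale factor (> 1); the study configuration uses 1.1
#' @return integer vector of strictly increasing block sizes, starting at
#'   \code{n_min} and ending at or below \code{n_max}
#' @examples
#' build_schedule(1, 5, 1.5)  # 1 2 3 5
#' build_schedule(1, 10, 2.0) # 1 2 4 8 10
#' @export
build_schedule <- function(n_min = 1, n_max = 540, s = 1.1) {
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 1L) stop("n_min must be >= 1")
  if (n_max <= n_min) stop("n_max must exceed n_min")
  if (!is.finite(s) || s <= 1) stop("scale factor s must be > 1")
  levels <- n_min
  n <- n_min
  repeat {
    n <- max(round_half_up(n * s), n + 1L)
    if (n > n_max) break
    levels <- c(levels, n)
  }
  if (levels[length(levels)] != n_max) levels <- c(levels, n_max)
  structure(as.integer(levels), n_min = n_min, n_max = n_max, s = s,
            class = "scale_schedule")
}

#' @export
print.scale_schedule <- function(x, ...) {
  cat(sprintf("<scale_schedule> %d levels, n = %d..%d, s = %g\n",
              length(x), attr(x, "n_min"), attr(x, "n_max"), attr(x, "s")))
  print(as.integer(x))
  invisible(x)
}

#' Aggregation curve over a scale schedule
#'
#' Computes the (mean, variance) log-log point for every scheduled block
#' size, using overlapping blocks: the stride between block starts is
#' \code{max(1, round_half_up(n * (1 - overlap)))}. Overlap increases the
#' number of segments the variance is estimated from at large n, where
#' non-overlapping aggregation leaves too few blocks for a stable estimate.
#' Degenerate levels (non-positive mean, which only an all-zero window can
#' produce, or zero variance) are dropped with a warning rather than failing
#' the curve.
#'
#' @param series a \code{count_series} or numeric vector
#' @param schedule a \code{\link{build_schedule}} result (or integer vector of
#'   block sizes)
#' @param overlap fraction of each block shared with the next, in [0, 0.75];
#'   0 reproduces non-overlapping aggregation, the default 0.5 doubles the
#'   segment count
#' @return data.frame of class \code{agg_curve} with columns
#'   \code{n, mean, variance, k_blocks, degenerate} (degenerate rows removed)
#' @export
compute_curve <- function(series, schedule = build_schedule(),
                          overlap = 0.5) {
  v <- as.numeric(series)
  if (!is.numeric(overlap) || overlap < 0 || overlap > 0.75)
    stop("overlap must lie in [0, 0.75]")
  lev <- as.integer(schedule)
  lev <- lev[lev <= length(v) %/% 2L]  # each level needs >= 2 blocks
  if (!length(lev)) stop("series too short for any scheduled level")
  rows <- lapply(lev, function(n) {
    stride <- max(1L, round_half_up(n * (1 - overlap)))
    summarize_level(aggregate_blocks(v, n, stride = stride), n = n)
  })
  curve <- do.call(rbind, rows)
  if (any(curve$degenerate)) {
    warning("dropping degenerate aggregation level(s) n = ",
            paste(curve$n[curve$degenerate], collapse = ", "),
            call. = FALSE)
    curve <- curve[!curve$degenerate, , drop = FALSE]
  }
  class(curve) <- c("agg_curve", "data.frame")
  curve
}

#' Cubic fit to the log-log mean-variance relation
#'
#' Fits log10(variance) as a third-order polynomial in log10(mean) by
#' ordinary least squares. A cubic is flexible enough to capture how the
#' allometric slope changes across scales while remaining robust; its
#' derivative gives a local slope (and hence a scale-local fractal
#' dimension) at any aggregation level inside the fitted range. The
#' predictor is centered before fitting, which keeps the normal equations
#' well-conditioned and makes the fitted local slope exactly invariant under
#' positive rescaling of the input series (which only translates both log
#' coordinates).
#'
#' @param curve an \code{\link{compute_curve}} result with >= 5 usable levels
#' @return object of class \code{loglog_fit}: centered polynomial
#'   coefficients, fit domain, and the per-level log10-mean lookup used to map
#'   an aggregation level n to its position on the curve
#' @export
fit_loglog <- function(curve) {
  if (nrow(curve) < 5L)
    stop("insufficient levels: cubic fit needs at least 5 log-log points, got ",
         nrow(curve))
  x <- log10(curve$mean)
  y <- log10(curve$variance)
  if (any(diff(x) <= 0))
    stop("log-means are not strictly increasing across levels; ",
         "cannot fit a single-valued mean-variance relation")
  x0 <- mean(x)
  xc <- x - x0
  X <- cbind(1, xc, xc^2, xc^3)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < 4L) stop("rank-deficient design (collinear log-means)")
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(coeffs = unname(fit$coefficients),
                 center = x0,
                 domain = range(x),
                 levels = curve$n,
                 level_log_means = x,
                 r_squared = r2,
                 curve = curve),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("<loglog_fit> cubic over %d levels (n = %d..%d), R^2 = %.5f\n",
              length(x$levels), min(x$levels), max(x$levels), x$r_squared))
  invisible(x)
}

# derivative of the centered cubic at log10-mean position xs
.loglog_slope_at <- function(fit, xs) {
  z <- xs - fit$center
  fit$coeffs[2L] + 2 * fit$coeffs[3L] * z + 3 * fit$coeffs[4L] * z^2
}

# map an aggregation level n to its log10-mean coordinate, interpolating
# log-linearly in (log n, log10 mean) between adjacent scheduled levels
.logmean_at_n <- function(fit, n) {
  lev <- fit$levels
  if (n < min(lev) || n > max(lev))
    stop("evaluation scale n = ", n, " lies outside the fitted range [",
         min(lev), ", ", max(lev), "]")
  hit <- match(n, lev)
  if (!is.na(hit)) return(fit$level_log_means[hit])
  stats::approx(log(lev), fit$level_log_means, xout = log(n))$y
}

#' Scale-local fractal dimension from a fitted log-log curve
#'
#' Evaluates the derivative of the cubic mean-variance fit at the position
#' corresponding to aggregation level \code{n}, giving the local allometric
#' slope b and the fractal dimension D = 2 - b/2 at that timescale. Levels
#' that were not in the schedule are located by log-linear interpolation of
#' log10(mean) against log(n) between the two adjacent scheduled levels (the
#' log-log plot is annotated at arbitrary n, e.g. n = 170 for a 3 h scale at
#' minute sampling, which need not be a scheduled level). No extrapolation
#' outside the fitted range is performed.
#'
#' @param fit a \code{\link{fit_loglog}} result
#' @param n evaluation scale in samples, inside the fitted level range
#' @param dt_sec sampling interval used to express the timescale (default 60)
#' @return one-row data.frame: \code{n, timescale_min, slope_b, D}
#' @export
local_fd <- function(fit, n, dt_sec = 60) {
  stopifnot(inherits(fit, "loglog_fit"))
  xs <- .logmean_at_n(fit, n)
  b <- .loglog_slope_at(fit, xs)
  data.frame(n = n, timescale_min = n * dt_sec / 60,
             slope_b = b, D = fd_from_slope(b))
}

#' Adapted allometric aggregation (one-shot)
#'
#' Runs the full adapted pipeline on a series: geometric scale schedule,
#' overlapping-block aggregation curve, cubic log-log fit. The returned fit
#' can be queried for the scale-local fractal dimension at any level via
#' \code{\link{local_fd}} or \code{\link{fd_profile}}.
#'
#' @param series a \code{count_series} or numeric vector
#' @param n_min,n_max,s schedule parameters (see \code{\link{build_schedule}});
#'   defaults n_min = 1, n_max = 540 (9 h at minute sampling), s = 1.1 follow
#'   the study configuration for 3-week recordings
#' @param overlap block overlap fraction (see \code{\link{compute_curve}})
#' @return a \code{loglog_fit}
#' @examples
#' x <- gen_iid(days = 3, seed = 1)
#' fit <- aaa(x, n_max = 256)
#' local_fd(fit, 64) # D near 1.5 for uncorrelated counts
#' @export
aaa <- function(series, n_min = 1, n_max = 540, s = 1.1, overlap = 0.5) {
  sched <- build_schedule(n_min, n_max, s)
  curve <- compute_curve(series, sched, overlap = overlap)
  fit <- fit_loglog(curve)
  fit$schedule <- sched
  fit$dt_sec <- if (inherits(series, "count_series")) dt_sec(series) else 60
  fit
}

#' Fractal-dimension profile across scales
#'
#' One aggregation pass, one cubic fit, then the scale-local fractal
#' dimension evaluated at each requested scale — the per-subject
#' dimension-versus-timescale curve.
#'
#' @param series a \code{count_series} or numeric vector
#' @param eval_scales evaluation scales in samples; default 30 min .. 8 h at
#'   minute sampling
#' @param n_min,n_max,s,overlap AAA parameters, as in \code{\link{aaa}}
#' @return data.frame of class \code{fd_profile} with one row per scale:
#'   \code{n, timescale_min, slope_b, D}
#' @export
fd_profile <- function(series, eval_scales = c(30, 60, 120, 180, 240, 360, 480),
                       n_min = 1, n_max = 540, s = 1.1, overlap = 0.5) {
  fit <- aaa(series, n_min, n_max, s, overlap)
  out <- do.call(rbind, lapply(eval_scales, function(n)
    local_fd(fit, n, dt_sec = fit$dt_sec)))
  class(out) <- c("fd_profile", "data.frame")
  attr(out, "fit") <- fit
  out
}
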