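#' Log-log mean-variance plot with the fitted cubic
#'
#' Scatter of the per-level (log10 mean, log10 variance) points with the
#' fitted third-order polynomial overlaid. Selected aggregation levels are
#' annotated with their timescale (n samples converted to minutes/hours), so
#' the scale a local slope refers to can be read off the curve.
#'
#' @param x a \code{loglog_fit}
#' @param annotate_n aggregation levels to annotate (default: about 5 spread
#'   over the schedule)
#' @param dt_sec sampling interval for timescale labels
#' @param ... passed to \code{plot}
#' @export
plot.loglog_fit <- function(x, annotate_n = NULL, dt_sec = 60, ...) {
  cx <- x$curve
  lx <- log10(cx$mean); ly <- log10(cx$variance)
  graphics::plot(lx, ly, pch = 19, cex = 0.6,
                 xlab = "log10 mean of block sums",
                 ylab = "log10 variance of block sums", ...)
  xs <- seq(x$domain[1L], x$domain[2L], length.out = 200)
  z <- xs - x$center
  ys <- x$coeffs[1L] + x$coeffs[2L] * z + x$coeffs[3L] * z^2 +
    x$coeffs[4L] * z^3
  graphics::lines(xs, ys, col = "steelblue", lwd = 2)
  if (is.null(annotate_n)) {
    ii <- unique(round(seq(1, length(x$levels), length.out = 5)))
    annotate_n <- x$levels[ii]
  }
  for (n in annotate_n) {
    i <- match(n, x$levels)
    if (is.na(i)) next
    lab <- if (n * dt_sec >= 3600)
      sprintf("n=%d (%.1f h)", n, n * dt_sec / 3600)
    else sprintf("n=%d (%d min)", n, round(n * dt_sec / 60))
    graphics::text(lx[i], ly[i], lab, pos = 4, cex = 0.7, col = "grey30")
  }
  invisible(x)
}

#' Fractal dimension versus timescale
#'
#' @param x an \code{fd_profile}
#' @param ... passed to \code{plot}
#' @export
plot.fd_profile <- function(x, ...) {
  graphics::plot(x$timescale_min / 60, x$D, type = "b", pch = 19, log = "x",
                 xlab = "timescale (hours)", ylab = "fractal dimension D",
                 ylim = range(c(x$D, 1, 1.5)), ...)
  graphics::abline(h = c(1, 1.5), lty = 3, col = "grey60")
  invisible(x)
}

#' Annotated complexity track
#'
#' Plots the windowed fractal dimension over time. Optional annotations:
#' weekly static fractal dimensions as dashed horizontal segments, and
#' weekly background shading by functioning rank (red/orange/green for
#' worst/average/best, ties shaded orange).
#'
#' @param x a \code{complexity_track}
#' @param weekly optional \code{\link{weekly_summaries}} result
#' @param ranking optional functioning labels/ranks for the three weeks
#' @param scale evaluation scale to plot when several are present
#' @param ... passed to \code{plot}
#' @export
plot.complexity_track <- function(x, weekly = NULL, ranking = NULL,
                                  scale = NULL, ...) {
  if (is.null(scale)) scale <- x$n[1L]
  tr <- x[x$n == scale & x$status == "ok", , drop = FALSE]
  days <- tr$end_index / (86400 / attr(x, "dt_sec"))
  graphics::plot(days, tr$D, type = "n",
                 xlab = "time since recording start (days)",
                 ylab = sprintf("fractal dimension (n = %s)", scale),
                 ylim = range(c(tr$D, 1, 1.5), na.rm = TRUE), ...)
  if (!is.null(ranking) && !is.null(weekly)) {
    fr <- functioning_ranks(ranking)
    cols <- grDevices::adjustcolor(
      c("firebrick", "orange", "forestgreen"), alpha.f = 0.15)
    shade <- cols[pmin(pmax(round(fr), 1L), 3L)]
    for (i in seq_len(nrow(weekly)))
      graphics::rect(weekly$first_day[i] - 1, graphics::par("usr")[3L],
                     weekly$last_day[i], graphics::par("usr")[4L],
                     col = shade[i], border = NA)
  }
  graphics::lines(days, tr$D, col = "steelblue")
  if (!is.null(weekly))
    for (i in seq_len(nrow(weekly)))
      graphics::segments(weekly$first_day[i] - 1, weekly$fd[i],
                         weekly$last_day[i], weekly$fd[i],
                         lty = 2, lwd = 2, col = "grey20")
  graphics::abline(h = c(1, 1.5), lty = 3, col = "grey60")
  invisible(x)
}
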