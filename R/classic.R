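#' Block-aggregate a count series
#'
#' Sums consecutive windows of \code{n} samples starting at positions
#' 1, 1+stride, 1+2*stride, ... Trailing samples that do not fill a complete
#' block are dropped (never padded, since padding would distort the block-sum
#' statistics). \code{stride = n} gives the classic non-overlapping
#' aggregation; \code{stride < n} gives overlapping blocks.
#'
#' @param series a \code{count_series} or numeric vector
#' @param n block size in samples, 1 <= n <= length(series)
#' @param stride step between block starts, 1 <= stride <= n
#' @return numeric vector of block sums, length \code{floor((N - n)/stride) + 1}
#' @examples
#' aggregate_blocks(c(1, 2, 3, 4), n = 2, stride = 2) # 3 7
#' aggregate_blocks(c(1, 2, 3, 4), n = 2, stride = 1) # 3 5 7
#' @export
aggregate_blocks <- function(series, n, stride = n) {
  v <- as.numeric(series)
  N <- length(v)
  n <- as.integer(n); stride <- as.integer(stride)
  if (n < 1L || n > N) stop("block size n must satisfy 1 <= n <= N")
  if (stride < 1L) stop("stride must be >= 1")
  if (stride > n) stop("stride must not exceed the block size")
  cs <- c(0, cumsum(v))
  starts <- seq.int(1L, N - n + 1L, by = stride)
  cs[starts + n] - cs[starts]
}

#' Mean/variance summary of one aggregation level
#'
#' Records the statistics the allometric aggregation method plots at each
#' scale: the mean and the sample variance (divisor k - 1) of the block sums,
#' together with the number of blocks. A level with zero variance (constant
#' block sums) or non-positive mean cannot contribute a log-log point and is
#' flagged \code{degenerate}.
#'
#' @param block_sums numeric vector of block sums (length >= 2)
#' @param n the block size the sums were computed at (carried along)
#' @return one-row data.frame: \code{n, mean, variance, k_blocks, degenerate}
#' @export
summarize_level <- function(block_sums, n = NA_integer_) {
  k <- length(block_sums)
  if (k < 2L) stop("need at least 2 blocks to estimate a variance")
  m <- mean(block_sums)
  v <- stats::var(block_sums)
  data.frame(n = as.integer(n), mean = m, variance = v, k_blocks = k,
             degenerate = (v <= 0 || m <= 0))
}

#' Convert a log-log mean-variance slope to a fractal dimension
#'
#' The allometric relation var Y(n) = a * mean(Y(n))^b links the slope b of
#' the log-log mean-variance plot to the fractal dimension D = 2 - b/2.
#' A slope of 1 (uncorrelated process) gives D = 1.5; a slope of 2 (fully
#' regular process) gives D = 1. Values outside [1, 1.5] are returned as-is:
#' D > 1.5 indicates anti-correlation, D < 1 super-regular scaling.
#'
#' @param b log-log slope (any real)
#' @return fractal dimension \code{2 - b/2}
#' @export
fd_from_slope <- function(b) 2 - b / 2

#' Classic (static) allometric aggregation
#'
#' The original estimator: aggregate into non-overlapping blocks for every
#' block size n = 1..n_max, plot log10 variance against log10 mean of the
#' block sums, fit a single straight line by ordinary least squares, and
#' convert its slope b to the fractal dimension D = 2 - b/2.
#'
#' @param series a \code{count_series} (or numeric vector)
#' @param n_max largest block size (>= 3); the series must contain at least
#'   two blocks at this size (N >= 2 * n_max)
#' @return a list of class \code{classic_fd} with elements \code{slope_b},
#'   \code{intercept_log_a}, \code{r_squared}, \code{D}, and \code{curve}
#'   (the per-level aggregation statistics)
#' @examples
#' x <- gen_iid(days = 2, seed = 1)
#' classic_fd(x, n_max = 32)$D # near 1.5
#' @export
classic_fd <- function(series, n_max) {
  v <- as.numeric(series)
  n_max <- as.integer(n_max)
  if (n_max < 3L) stop("n_max must be at least 3")
  if (length(v) < 2L * n_max)
    stop("series too short: need N >= 2 * n_max so every level has >= 2 blocks")
  curve <- do.call(rbind, lapply(seq_len(n_max), function(n)
    summarize_level(aggregate_blocks(v, n, stride = n), n = n)))
  bad <- which(curve$degenerate)
  if (length(bad))
    stop("degenerate aggregation level(s) n = ",
         paste(curve$n[bad], collapse = ", "),
         " (zero variance or non-positive mean)")
  x <- log10(curve$mean)
  y <- log10(curve$variance)
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients[2L])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(slope_b = b,
                 intercept_log_a = unname(fit$coefficients[1L]),
                 r_squared = r2,
                 D = fd_from_slope(b),
                 n_max = n_max,
                 curve = curve),
            class = "classic_fd")
}

#' @export
print.classic_fd <- function(x, ...) {
  cat(sprintf(
    "<classic allometric aggregation> n = 1..%d (non-overlapping)\n", x$n_max))
  cat(sprintf("  slope b = %.4f, D = %.4f, R^2 = %.4f\n",
              x$slope_b, x$D, x$r_squared))
  invisible(x)
}
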