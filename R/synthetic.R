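# Evaluate expr with the RNG seeded at `seed`, restoring the global RNG
# state afterwards so generators never perturb user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

.default_start <- function() as.POSIXct("1970-01-01", tz = "UTC")

#' Uncorrelated (i.i.d.) synthetic count series
#'
#' Minute-resolution independent draws — the reference signal for which the
#' allometric log-log slope is 1 and the fractal dimension 1.5 at every
#' scale.
#'
#' @param days recording length in days (each day is 1440 minute samples)
#' @param seed RNG seed; the same (parameters, seed) pair always yields a
#'   bit-identical series
#' @param dist "poisson" (rate \code{lambda}) or "uniform" (on
#'   \code{[min, max]})
#' @param lambda Poisson rate (default 100, a plausible mean minute count)
#' @param min,max uniform bounds (used when \code{dist = "uniform"})
#' @param start_time series start (default 1970-01-01 UTC)
#' @return a \code{count_series} of \code{days * 1440} samples
#' @export
gen_iid <- function(days = 21, seed = 1, dist = c("poisson", "uniform"),
                    lambda = 100, min = 0, max = 200,
                    start_time = .default_start()) {
  dist <- match.arg(dist)
  N <- as.integer(round(days * 1440))
  v <- with_seed(seed, switch(dist,
    poisson = {
      if (lambda <= 0) stop("lambda must be positive")
      stats::rpois(N, lambda)
    },
    uniform = {
      if (max <= min || min < 0) stop("need 0 <= min < max")
      stats::runif(N, min, max)
    }))
  count_series(v, start_time = start_time)
}

#' Fully regular (deterministic) synthetic series
#'
#' Deterministic signals for which block sums scale with variance
#' proportional to n^2 and mean proportional to n, so the allometric slope
#' is 2 and the fractal dimension 1. Two variants: a linear ramp
#' \code{y_i = intercept + slope * (i - 1)} and a smooth 24 h-periodic
#' profile. A constant signal (slope 0 on the ramp) has zero variance at
#' every level and is rejected by the aggregation fit; the generator warns.
#'
#' @param days recording length in days
#' @param kind "ramp" or "periodic"
#' @param slope,intercept ramp parameters (slope >= 0)
#' @param level,amplitude periodic-profile mean level and swing
#'   (\code{level > amplitude >= 0} keeps the signal positive)
#' @param start_time series start
#' @return a \code{count_series}
#' @export
gen_regular <- function(days = 21, kind = c("ramp", "periodic"),
                        slope = 1, intercept = 0,
                        level = 100, amplitude = 80,
                        start_time = .default_start()) {
  kind <- match.arg(kind)
  N <- as.integer(round(days * 1440))
  v <- switch(kind,
    ramp = {
      if (slope < 0) stop("slope must be >= 0")
      if (slope == 0)
        warning("constant signal: zero variance at every aggregation level; ",
                "the allometric fit will reject it", call. = FALSE)
      intercept + slope * (seq_len(N) - 1)
    },
    periodic = {
      if (amplitude < 0 || level <= amplitude)
        stop("need level > amplitude >= 0 for a positive periodic signal")
      i <- seq_len(N) - 1
      level + amplitude * sin(2 * pi * i / 1440)
    })
  count_series(v, start_time = start_time)
}

#' Short-memory AR(1) synthetic count series
#'
#' First-order autoregressive fluctuations around a positive offset:
#' \code{y_i = max(0, offset + x_i)}, \code{x_i = phi * x_{i-1} + eps_i} with
#' Gaussian innovations, initialised from the stationary distribution.
#' Positive \code{phi} makes consecutive samples dependent, which adds a
#' covariance term to the variance of aggregated blocks at small n and
#' steepens the allometric log-log slope above 1.
#'
#' @param days recording length in days
#' @param seed RNG seed
#' @param phi AR coefficient, |phi| < 1
#' @param offset additive level keeping counts positive (default 100)
#' @param sd innovation standard deviation (default 10; stationary sd
#'   \code{sd/sqrt(1 - phi^2)})
#' @param start_time series start
#' @return a \code{count_series}; attribute \code{clip_fraction} records the
#'   share of samples clipped at zero
#' @export
gen_ar1 <- function(days = 21, seed = 1, phi = 0.9, offset = 100, sd = 10,
                    start_time = .default_start()) {
  if (abs(phi) >= 1) stop("need |phi| < 1 for stationarity")
  if (sd <= 0) stop("innovation sd must be positive")
  N <- as.integer(round(days * 1440))
  x <- with_seed(seed, {
    init <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
    as.numeric(stats::filter(stats::rnorm(N, 0, sd), phi,
                             method = "recursive", init = init))
  })
  y <- offset + x
  clip <- mean(y < 0)
  if (clip > 0.01)
    warning(sprintf("%.1f%% of samples clipped at zero; raise the offset",
                    100 * clip), call. = FALSE)
  out <- count_series(pmax(y, 0), start_time = start_time)
  attr(out, "clip_fraction") <- clip
  out
}

#' Exact fractional Gaussian noise autocovariance
#'
#' Closed form \code{gamma(k) = sigma^2/2 * (|k+1|^{2H} - 2|k|^{2H} +
#' |k-1|^{2H})} for unit-spaced fGn with Hurst exponent H. Serves as the
#' analytic reference the simulator is validated against.
#'
#' @param k nonnegative integer lag(s)
#' @param H Hurst exponent in (0, 1)
#' @param sigma marginal standard deviation (default 1)
#' @return autocovariance at each lag
#' @export
fgn_autocov <- function(k, H, sigma = 1) {
  0.5 * sigma^2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                     abs(k - 1)^(2 * H))
}

# Exact fGn sample path by Davies-Harte circulant embedding: embed the
# Toeplitz autocovariance in a circulant of order 2M (M the next power of
# two >= N), whose eigenvalues come from one FFT; a complex Gaussian vector
# shaped by sqrt(eigenvalues) transforms back to a Gaussian vector with
# exactly the target autocovariance. Errors out if the embedding is not
# nonnegative definite rather than approximating silently.
.fgn_sim <- function(N, H) {
  if (H <= 0 || H >= 1) stop("Hurst exponent must lie in (0, 1)")
  M <- 2^ceiling(log2(N))
  g <- fgn_autocov(0:M, H)
  r <- c(g, g[M:2])                      # circulant first row, length 2M
  lambda <- Re(stats::fft(r))
  tol <- -1e-8 * max(lambda)
  if (any(lambda < tol))
    stop("circulant embedding not nonnegative definite for H = ", H)
  lambda[lambda < 0] <- 0
  m <- 2L * M
  a <- complex(m)
  a[1] <- sqrt(lambda[1]) * stats::rnorm(1)
  a[M + 1] <- sqrt(lambda[M + 1]) * stats::rnorm(1)
  u <- stats::rnorm(M - 1)
  w <- stats::rnorm(M - 1)
  k <- 2:M
  a[k] <- sqrt(lambda[k] / 2) * complex(real = u, imaginary = w)
  a[m + 2 - k] <- Conj(a[k])
  Re(stats::fft(a))[seq_len(N)] / sqrt(m)
}

#' Long-memory synthetic counts driven by exact fractional Gaussian noise
#'
#' \code{y_i = max(0, offset + sigma * fGn_i(H))} at minute resolution. The
#' fGn path is simulated exactly (circulant embedding), so its block sums
#' obey \code{Var = sigma^2 * n^{2H}} without method error, making the
#' series a parameter-recovery oracle: the allometric slope is 2H and the
#' fractal dimension 2 - H.
#'
#' @param days recording length in days
#' @param seed RNG seed
#' @param H Hurst exponent in (0, 1); H = 0.5 reduces to i.i.d. Gaussian
#' @param offset additive level (default 100)
#' @param sigma fGn standard deviation (default 20; with offset 100 the
#'   zero-clip fraction is negligible)
#' @param start_time series start
#' @return a \code{count_series} with attribute \code{clip_fraction}
#' @export
gen_fgn <- function(days = 21, seed = 1, H = 0.8, offset = 100, sigma = 20,
                    start_time = .default_start()) {
  N <- as.integer(round(days * 1440))
  z <- with_seed(seed, .fgn_sim(N, H))
  y <- offset + sigma * z
  clip <- mean(y < 0)
  if (clip > 0.01)
    warning(sprintf("%.1f%% of samples clipped at zero; raise the offset",
                    100 * clip), call. = FALSE)
  out <- count_series(pmax(y, 0), start_time = start_time)
  attr(out, "clip_fraction") <- clip
  out
}

#' Diurnal activity-like synthetic count series
#'
#' Emulates the gross structure of a multi-week wrist-actigraphy recording:
#' a 24 h-periodic alternation between a sleep span with near-zero counts
#' and a wake span with elevated, noisy counts, plus randomly placed
#' activity bouts (episodes of raised intensity, e.g. walking or household
#' activity). The day is indexed from the recording start. What it does not
#' emulate: non-wear gaps, weekday/weekend structure, or any long-memory
#' component beyond the daily cycle itself.
#'
#' @param days recording length in days
#' @param seed RNG seed
#' @param day_level mean minute count during wake (default 200)
#' @param night_level mean minute count during sleep (default 2)
#' @param sleep_start_hour hour-of-(recording-)day sleep begins (default 23)
#' @param sleep_hours sleep span length in hours, < 24 (default 8)
#' @param bouts_per_day expected number of activity bouts per day
#' @param bout_mean_minutes mean bout duration (geometric)
#' @param bout_gain multiplicative intensity during a bout (default 2.5)
#' @param start_time series start
#' @return a \code{count_series} of \code{days * 1440} samples
#' @export
gen_diurnal <- function(days = 21, seed = 1, day_level = 200, night_level = 2,
                        sleep_start_hour = 23, sleep_hours = 8,
                        bouts_per_day = 4, bout_mean_minutes = 30,
                        bout_gain = 2.5, start_time = .default_start()) {
  if (sleep_hours <= 0 || sleep_hours >= 24)
    stop("sleep span must lie strictly within 24 h")
  if (day_level <= night_level || night_level < 0)
    stop("need day_level > night_level >= 0")
  N <- as.integer(round(days * 1440))
  minute_of_day <- (seq_len(N) - 1L) %% 1440L
  s0 <- round(sleep_start_hour * 60) %% 1440
  s1 <- (s0 + round(sleep_hours * 60)) %% 1440
  asleep <- if (s0 < s1) minute_of_day >= s0 & minute_of_day < s1
            else minute_of_day >= s0 | minute_of_day < s1
  # smooth within-wake modulation: activity builds after waking, dips at night
  wake_len <- 1440 - round(sleep_hours * 60)
  wake_pos <- ((minute_of_day - s1) %% 1440) / wake_len   # 0..1 through wake
  rate <- ifelse(asleep, night_level,
                 day_level * (0.6 + 0.4 * sin(pi * pmin(wake_pos, 1))))
  v <- with_seed(seed, {
    nb <- stats::rpois(1, bouts_per_day * days)
    if (nb > 0) {
      wake_idx <- which(!asleep)
      starts <- sort(sample(wake_idx, nb, replace = TRUE))
      durs <- 1 + stats::rgeom(nb, 1 / bout_mean_minutes)
      for (j in seq_len(nb)) {
        span <- starts[j]:min(starts[j] + durs[j] - 1L, N)
        rate[span] <- rate[span] * bout_gain
      }
    }
    stats::rpois(N, rate)
  })
  count_series(v, start_time = start_time)
}

#' Inject a short high-intensity bout into a series
#'
#' Replaces \code{duration} consecutive samples with Poisson draws at a high
#' rate, emulating an episode of intense exercise (a short activity peak that
#' interrupts the regular organisation of the signal and pushes the local
#' fractal dimension toward the uncorrelated value of 1.5).
#'
#' @param series a \code{count_series}
#' @param start 1-based sample index of the bout start
#' @param duration bout length in samples (default 30)
#' @param level Poisson rate during the bout (e.g. 20x the wake level)
#' @param seed RNG seed for the bout draws
#' @return the modified \code{count_series}
#' @export
inject_bout <- function(series, start, duration = 30, level = 4000,
                        seed = 1) {
  stopifnot(inherits(series, "count_series"))
  start <- as.integer(start); duration <- as.integer(duration)
  if (start < 1L || start + duration - 1L > length(series))
    stop("bout does not fit inside the series")
  v <- as.numeric(series)
  v[start:(start + duration - 1L)] <-
    with_seed(seed, stats::rpois(duration, level))
  count_series(v, start_time = start_time(series), dt_sec = dt_sec(series))
}
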