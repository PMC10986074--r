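test_that("the geometric schedule follows the round-half-up recurrence", {
  expect_identical(as.integer(build_schedule(1, 5, 1.5)), c(1L, 2L, 3L, 5L))
  expect_identical(as.integer(build_schedule(1, 10, 2.0)),
                   c(1L, 2L, 4L, 8L, 10L))
  expect_error(build_schedule(1, 1, 1.1), "exceed")
  expect_error(build_schedule(1, 10, 1.0), "s must be")
  expect_error(build_schedule(0, 10, 1.5), "n_min")
})

test_that("schedules are strictly increasing and bounded for any s > 1", {
  set.seed(2)
  for (rep in 1:30) {
    s <- 1 + runif(1, 0.001, 2)
    n_max <- sample(5:600, 1)
    lev <- as.integer(build_schedule(1, n_max, s))
    expect_true(all(diff(lev) > 0))
    expect_identical(lev[1], 1L)
    expect_identical(lev[length(lev)], as.integer(n_max))
    expect_identical(anyDuplicated(lev), 0L)
  }
})

test_that("overlapping aggregation uses stride round_half_up(n*(1-overlap))", {
  expect_equal(aggregate_blocks(1:6, n = 2, stride = 1), c(3, 5, 7, 9, 11))
  curve <- compute_curve(1:6, schedule = c(1L, 2L), overlap = 0.5)
  expect_equal(curve$mean[curve$n == 2], mean(c(3, 5, 7, 9, 11)))
  expect_equal(curve$k_blocks[curve$n == 2], 5L)
})

test_that("zero overlap reproduces non-overlapping aggregation at each level", {
  set.seed(4)
  v <- rpois(500, 30)
  sched <- build_schedule(1, 32, 1.5)
  curve <- compute_curve(v, sched, overlap = 0)
  for (i in seq_len(nrow(curve))) {
    ref <- brute_block_sums(v, curve$n[i], curve$n[i])
    expect_equal(curve$mean[i], mean(ref))
    expect_equal(curve$variance[i], var(ref))
  }
})

test_that("level means of an i.i.d. series scale with n up to tail effects", {
  set.seed(5)
  v <- rpois(100, 40)
  curve <- compute_curve(v, c(1L, 2L, 4L, 8L), overlap = 0.5)
  for (i in seq_len(nrow(curve))) {
    n <- curve$n[i]
    # block means stay within the range of n * (running means of the data)
    expect_lt(abs(curve$mean[i] / n - mean(v)), 3)
  }
})

test_that("the cubic fit contains and recovers polynomial relations exactly", {
  x <- seq(0.5, 3, length.out = 8)
  line <- data.frame(n = 1:8, mean = 10^x, variance = 10^(1.3 * x + 0.2),
                     k_blocks = 10L, degenerate = FALSE)
  fit <- fit_loglog(line)
  # quadratic and cubic terms vanish; local slope 1.3 everywhere
  expect_lt(abs(fit$coeffs[3]), 1e-8)
  expect_lt(abs(fit$coeffs[4]), 1e-8)
  for (n in c(1, 2.5, 7)) {
    est <- local_fd(fit, n)
    expect_equal(est$slope_b, 1.3, tolerance = 1e-8)
    expect_equal(est$D, 1.35, tolerance = 1e-8)
  }

  ycub <- 0.1 * x^3 - 0.4 * x^2 + 1.7 * x + 0.3
  cub <- data.frame(n = 1:8, mean = 10^x, variance = 10^ycub,
                    k_blocks = 10L, degenerate = FALSE)
  fitc <- fit_loglog(cub)
  # recover the derivative of the generating cubic at interior points
  for (i in c(2, 4, 6)) {
    b_true <- 0.3 * x[i]^2 - 0.8 * x[i] + 1.7
    expect_equal(local_fd(fitc, i)$slope_b, b_true, tolerance = 1e-8)
  }

  expect_error(fit_loglog(line[1:4, ]), "insufficient levels")
})

test_that("evaluation outside the fitted scale range is refused", {
  fit <- aaa(gen_iid(days = 2, seed = 1), n_max = 64)
  expect_error(local_fd(fit, 100), "outside the fitted range")
  expect_error(local_fd(fit, 0.5), "outside the fitted range")
})

test_that("the local dimension satisfies D = 2 - b/2 exactly", {
  fit <- aaa(gen_iid(days = 2, seed = 2), n_max = 64)
  for (n in c(1, 5, 17, 64)) {
    est <- local_fd(fit, n)
    expect_identical(est$D, 2 - est$slope_b / 2)
  }
})

test_that("fd_profile is flat near 1.5 for i.i.d. and near 1.0 for a ramp", {
  # single-seed profiles wobble at the scales near n_max (few blocks per
  # window there), so flatness is asserted on the seed-averaged profile
  profs <- vapply(1:10, function(s)
    fd_profile(gen_iid(days = 21, seed = s), n_max = 540)$D, numeric(7))
  expect_lt(max(abs(rowMeans(profs) - 1.5)), 0.07)

  pr <- fd_profile(count_series(1:30240), n_max = 540)
  expect_true(all(abs(pr$D - 1.0) < 0.05))
})

test_that("the profile is invariant under positive rescaling to 1e-9", {
  x <- gen_diurnal(days = 7, seed = 3)
  p1 <- fd_profile(x, eval_scales = c(30, 90, 180, 300), n_max = 360)
  for (c0 in c(0.01, 3.7, 1000)) {
    p2 <- fd_profile(count_series(as.numeric(x) * c0),
                     eval_scales = c(30, 90, 180, 300), n_max = 360)
    expect_equal(p1$D, p2$D, tolerance = 1e-9)
  }
})

test_that("fractal dimension is non-decreasing across scales on diurnal signals", {
  for (s in 1:3) {
    p <- fd_profile(gen_diurnal(days = 21, seed = s),
                    eval_scales = c(30, 60, 120, 180, 240, 360, 480))
    expect_true(all(diff(p$D) > -1e-6), info = paste("seed", s))
  }
})

test_that("shuffling a long-memory series moves D back toward 1.5", {
  raised <- vapply(1:10, function(s) {
    x <- gen_fgn(days = 7, seed = s, H = 0.9)
    d0 <- local_fd(aaa(x, n_max = 256), 64)$D
    set.seed(s + 1000)
    dsh <- local_fd(aaa(count_series(sample(as.numeric(x))), n_max = 256),
                    64)$D
    dsh > d0
  }, logical(1))
  expect_gte(sum(raised), 9)
})

test_that("overlap is a variance-reduction device, not a bias", {
  for (s in 1:3) {
    x <- gen_iid(days = 21, seed = s)
    d0 <- local_fd(aaa(x, n_max = 256, overlap = 0), 64)$D
    d5 <- local_fd(aaa(x, n_max = 256, overlap = 0.5), 64)$D
    expect_lt(abs(d0 - d5), 0.03)
  }
  expect_error(compute_curve(1:100, c(1L, 2L), overlap = 0.9), "overlap")
})

test_that("degenerate levels are dropped with a warning, not a failure", {
  vv <- rep(5, 400)  # constant: zero variance at every level
  expect_warning(curve <- compute_curve(vv, build_schedule(1, 16, 1.5)),
                 "degenerate")
  expect_equal(nrow(curve), 0L)
  expect_error(fit_loglog(curve), "insufficient levels")
})
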