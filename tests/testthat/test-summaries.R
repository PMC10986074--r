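test_that("week spans partition the recording without overlap", {
  sp <- week_spans(21)
  expect_identical(sp$first_day, c(1L, 8L, 15L))
  expect_identical(sp$last_day, c(7L, 14L, 21L))
  sp14 <- week_spans(20, week3_from_day14 = TRUE)
  expect_identical(sp14$first_day[3], 14L)
  expect_error(week_spans(10), "at least 15")
})

test_that("three identical synthetic weeks give three equal dimensions", {
  wk <- gen_diurnal(days = 7, seed = 21)
  x <- count_series(rep(as.numeric(wk), 3))
  ws <- weekly_summaries(x)
  expect_equal(ws$fd[1], ws$fd[2], tolerance = 1e-12)
  expect_equal(ws$fd[2], ws$fd[3], tolerance = 1e-12)
  expect_equal(ws$total_counts[1], ws$total_counts[3])
})

test_that("daily statistics of a constant week are exact", {
  x <- count_series(c(rep(3, 20 * 1440), rpois(1440, 100)))
  ds <- daily_sums(slice_days(x, 1, 7))
  expect_equal(ds, rep(1440 * 3, 7))
  expect_equal(sd(ds), 0)
})

test_that("weekly dimensions of i.i.d. weeks stay near 1.5", {
  fds <- c()
  for (s in 1:3) {
    ws <- weekly_summaries(gen_iid(days = 21, seed = s), n_max = 540,
                           eval_scale = 180)
    # a single 7-day week gives a noisy 3 h estimate under a 9 h schedule;
    # individual weeks stay in a band, their ensemble centres on 1.5
    expect_true(all(ws$fd > 1.35 & ws$fd < 1.65), info = paste("seed", s))
    expect_equal(ws$daily_mean, rep(1440 * 100, 3), tolerance = 0.01)
    fds <- c(fds, ws$fd)
  }
  expect_lt(abs(mean(fds) - 1.5), 0.06)
})

test_that("weekly summaries show no leakage across week boundaries", {
  x <- gen_diurnal(days = 21, seed = 8)
  ws <- weekly_summaries(x)
  for (i in 1:3) {
    wk <- slice_days(x, ws$first_day[i], ws$last_day[i])
    est <- local_fd(aaa(wk), 180)
    expect_equal(ws$fd[i], est$D, tolerance = 1e-12)
    expect_equal(ws$total_counts[i], sum(as.numeric(wk)))
  }
})

test_that("the global dimension is deterministic and summarises the weeks", {
  x <- gen_iid(days = 21, seed = 4)
  g1 <- global_fd(x)
  g2 <- global_fd(x)
  expect_identical(g1, g2)
  ws <- weekly_summaries(x)
  # soft expectation on a smooth fixture: global near the weekly band
  expect_lt(abs(g1$D - mean(ws$fd)), 0.1)
})

test_that("complexity-activity correlation handles exact and degenerate cases", {
  x <- gen_iid(days = 10, seed = 6)
  tr <- run_taaa(x, window_spec(4320, 480), n_max = 256, eval_scales = 64)

  # affine fixture with negative gain -> r = -1 exactly
  tr_affine <- tr
  cs <- c(0, cumsum(as.numeric(x)))
  act <- cs[tr$end_index + 1] - cs[tr$end_index - 4320 + 1]
  tr_affine$D <- 2 - act * 1e-8
  res <- fd_activity_correlation(x, tr_affine)
  expect_equal(res$r, -1, tolerance = 1e-12)

  # constant track -> zero variance -> NA with a warning
  tr_const <- tr
  tr_const$D[] <- 1.3
  expect_warning(res0 <- fd_activity_correlation(x, tr_const),
                 "zero variance")
  expect_true(is.na(res0$r))
})

test_that("complexity-activity correlation is negative on activity-dependent fixtures", {
  # days alternate sedentary/active; active days get proportionally smoother
  # (more regular) signals, tying high counts to low D as in wrist actigraphy
  set.seed(13)
  days <- 12
  v <- unlist(lapply(seq_len(days), function(d) {
    if (d %% 2 == 0) 400 + cumsum(rnorm(1440, 0, 2))    # active, persistent
    else rpois(1440, 120)                               # sedentary, noisy
  }))
  x <- count_series(pmax(v, 0))
  tr <- suppressWarnings(
    run_taaa(x, window_spec(4320, 480), n_max = 360, eval_scales = 120))
  res <- fd_activity_correlation(x, tr)
  expect_lt(res$r, 0)
})

test_that("Pearson correlation is invariant to affine rescaling of inputs", {
  set.seed(3)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  expect_equal(cor(a, b), cor(10 + 3 * a, b), tolerance = 1e-12)
  expect_equal(cor(a, b), cor(a, -2 * b + 1) * -1, tolerance = 1e-12)
})

test_that("functioning labels map to average-rank ordinals", {
  expect_equal(functioning_ranks(c("worst", "average", "best")), c(1, 2, 3))
  expect_equal(functioning_ranks(c("average", "best", "average")),
               c(1.5, 3, 1.5))
  expect_equal(functioning_ranks(c(2, 3, 1)), c(2, 3, 1))
  expect_error(functioning_ranks(c("bad", "good", "ok")), "labels")
})

test_that("rank correlation inverts the dimension for the complexity ranking", {
  wk <- data.frame(fd = c(1.29, 1.28, 1.27), total_counts = c(10, 20, 30))
  res <- functioning_rank_correlation(c(1, 2, 3), wk, "complexity")
  expect_equal(res$rho, 1)
  expect_lt(res$p_value, 0.001)

  wk2 <- data.frame(fd = c(1.27, 1.28, 1.29), total_counts = c(10, 20, 30))
  res2 <- functioning_rank_correlation(c(1, 2, 3), wk2, "complexity")
  expect_equal(res2$rho, -1)

  res3 <- functioning_rank_correlation(c(1, 2, 3), wk, "activity")
  expect_equal(res3$rho, 1)
})

test_that("a partial ranking caps the attainable correlation at 0.866", {
  for (p in perm3) {
    res <- functioning_rank_correlation(c(1, 2.5, 2.5),
                                        data.frame(fd = c(1.3, 1.2, 1.1)[p],
                                                   total_counts = 1:3),
                                        "complexity")
    expect_lte(abs(res$rho), sqrt(3) / 2 + 1e-9)
  }
})

test_that("3-item Spearman values and p-values are exhaustively quantised", {
  # untied rankings: rho in {-1, -0.5, 0.5, 1}
  seen <- c()
  for (p in perm3) for (q in perm3) {
    r <- spearman_small(p, q)
    seen <- c(seen, r$rho)
    if (abs(r$rho) == 1) expect_lt(r$p_value, 0.001)
    else expect_gt(r$p_value, 0.3)
  }
  expect_setequal(round(sort(unique(seen)), 6), c(-1, -0.5, 0.5, 1))

  # one tied pair: rho in {-0.866, 0, 0.866}
  tied <- list(c(1, 2.5, 2.5), c(2.5, 1, 2.5), c(2.5, 2.5, 1),
               c(1.5, 1.5, 3), c(1.5, 3, 1.5), c(3, 1.5, 1.5))
  seen_t <- c()
  for (tv in tied) for (q in perm3) {
    r <- spearman_small(tv, q)
    seen_t <- c(seen_t, r$rho)
    expect_gte(r$p_value, 0.3)  # a tie never reaches significance on 3 items
  }
  expect_setequal(round(sort(unique(seen_t)), 3), c(-0.866, 0, 0.866))

  # printed-table pattern: p approx 0.33 at |rho| = 0.866, 0.67 at 0.5
  expect_equal(spearman_small(c(1, 2.5, 2.5), c(1, 2, 3))$p_value, 1 / 3,
               tolerance = 1e-9)
  expect_equal(spearman_small(c(1, 2, 3), c(1, 3, 2))$p_value, 2 / 3,
               tolerance = 1e-9)
})
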