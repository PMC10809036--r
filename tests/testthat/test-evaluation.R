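test_that("match_events applies the 1-s tolerance chronologically", {
  m <- match_events(10, 10.4)
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))

  m2 <- match_events(10, 11.5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 1L, 1L))

  m3 <- match_events(c(10, 12), c(10.1, 11.9, 14))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(2L, 1L, 0L))
})

test_that("match counts satisfy their accounting identities", {
  set.seed(51)
  for (i in 1:30) {
    a <- sort(runif(sample(0:6, 1), 0, 20))
    b <- sort(runif(sample(0:6, 1), 0, 20))
    m <- match_events(a, b)
    expect_equal(m$tp + m$fn, length(a))
    expect_equal(m$tp + m$fp, length(b))
    # greedy-chronological matching never exceeds the optimal matching size
    # (it can fall short of it in rare crowded configurations; see the
    # decisions ledger -- the published procedure is the greedy one)
    expect_lte(m$tp, bf_max_matches(a, b, tol = 1))
    # swapped roles keep the accounting identities
    m_sw <- match_events(b, a)
    expect_equal(m_sw$tp + m_sw$fn, length(b))
    expect_equal(m_sw$tp + m_sw$fp, length(a))
  }
})

test_that("greedy matching agrees with brute-force optimum on sparse events", {
  # at realistic event spacing (>= 2 s apart, 1-s tolerance) greedy = optimal
  set.seed(58)
  for (i in 1:20) {
    a <- cumsum(2 + rexp(5, 1))
    b <- a + runif(5, -1.4, 1.4)
    m <- match_events(a, sort(b))
    expect_equal(m$tp, bf_max_matches(a, sort(b), tol = 1))
  }
})

test_that("accuracy and F1 reproduce the published count arithmetic", {
  c1 <- list(tp = 139, fp = 15, fn = 5)
  expect_equal(accuracy(c1), 139 / 159, tolerance = 1e-12)
  expect_equal(accuracy(c1), 0.8742, tolerance = 1e-4)
  expect_equal(f1_score(c1), sqrt((139 / 144) * (139 / 154)), tolerance = 1e-12)
  expect_equal(f1_score(c1), 0.9334, tolerance = 1e-4)
  expect_equal(f1_score(c1, method = "product"), (139 / 144) * (139 / 154),
               tolerance = 1e-12)

  perfect <- list(tp = 10, fp = 0, fn = 0)
  expect_equal(accuracy(perfect), 1)
  expect_equal(f1_score(perfect), 1)

  expect_equal(f1_score(list(tp = 0, fp = 3, fn = 2)), 0)
  expect_error(accuracy(list(tp = 0, fp = 0, fn = 0)), "undefined")
  expect_error(f1_score(list(tp = 0, fp = 0, fn = 0)), "undefined")
})

test_that("poisson baseline is 0 without events and grows with rate", {
  expect_equal(poisson_baseline(numeric(0), 600), 0)
  set.seed(52)
  rates <- c(0.01, 0.05, 0.2)
  base <- vapply(rates, function(r) {
    manual <- sort(runif(round(r * 600), 0, 600))
    poisson_baseline(manual, 600, n_reps = 200, rng_seed = 53)
  }, numeric(1))
  expect_true(all(diff(base) > 0))
  expect_lt(max(base), 0.5)
})

test_that("compute_snr follows the peak/spread definition", {
  fr <- 10
  set.seed(54)
  base <- runif(1200, 0, 0.2)
  x <- base
  peaks_at <- c(300, 600, 900)
  x[peaks_at] <- 5
  rec <- compute_snr(x, fr, preictal_window = c(0, 119))
  expect_equal(rec$n_peaks, 3L)
  expected <- 5 / unname(diff(quantile(x[1:1191], c(0.1, 0.4))))
  expect_equal(rec$snr, expected, tolerance = 0.02)

  # scale invariance
  rec2 <- compute_snr(3 * x, fr, preictal_window = c(0, 119))
  expect_equal(rec2$snr, rec$snr, tolerance = 1e-10)

  # no peak above 1 dff prominence: undefined, flagged
  rec3 <- compute_snr(base, fr, preictal_window = c(0, 119))
  expect_true(is.na(rec3$snr))
  expect_equal(rec3$n_peaks, 0L)
})

test_that("snr regression recovers planted relations", {
  snr <- seq(1, 10, length.out = 50)
  # exact linear data: lm warns about a perfect fit, which is the point here
  fit <- suppressWarnings(snr_performance_regression(0.1 + 0.05 * snr, snr))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$slope, 0.05, tolerance = 1e-10)

  set.seed(55)
  noisy <- pmin(1, pmax(0, 0.2 + 0.06 * snr + rnorm(50, 0, 0.05)))
  fit2 <- snr_performance_regression(noisy, snr)
  expect_gt(fit2$slope, 0)
  expect_lt(fit2$p_value, 0.01)

  # SNR-independent F1: slope ~ 0, p typically > 0.05
  set.seed(56)
  flat <- rep(0.5, 50) + rnorm(50, 0, 0.05)
  fit3 <- snr_performance_regression(flat, snr)
  expect_lt(abs(fit3$slope), 0.01)
  expect_gt(fit3$p_value, 0.05)

  expect_error(snr_performance_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(snr_performance_regression(c(1, 2, 3), c(2, 2, 2)), "degenerate")
})

test_that("bootstrap_ci brackets the estimate deterministically under a seed", {
  x <- c(0.2, 0.5, 0.6, 0.7, 0.75, 0.8, 0.9, 0.95)
  ci1 <- bootstrap_ci(x, median, n_boot = 500, rng_seed = 57)
  ci2 <- bootstrap_ci(x, median, n_boot = 500, rng_seed = 57)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$estimate)
  expect_gte(ci1$upper, ci1$estimate)
  expect_equal(ci1$estimate, median(x))
})

test_that("per_cell_f1 scores recruitment tables per cell", {
  recr <- data.frame(cell = c(1, 1, 2), event_type = "pis",
                     seed_time = c(10, 20, 10), recruited = TRUE,
                     recruitment_time = c(10.1, 20.2, 15),
                     feature = 1, peak_z = 5, mean_ratio = NA)
  truth <- data.frame(cell = c(1, 1, 2), time = c(10, 20, 10))
  out <- per_cell_f1(recr, truth)
  expect_equal(out$f1[out$cell == 1], 1)
  expect_equal(out$f1[out$cell == 2], 0)   # detection 5 s off: fp + fn
})
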