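test_that("model_spike_integral is the Gaussian area", {
  expect_equal(model_spike_integral(1, 0.33), 0.33 * sqrt(2 * pi))
  expect_equal(model_spike_integral(1, 0.33), 0.8272, tolerance = 1e-4)
  expect_equal(model_spike_integral(2, 0.33), 2 * model_spike_integral(1, 0.33))
  expect_equal(model_spike_integral(1, 0), 0)
})

test_that("population spike detection recovers planted spikes at steepest slope", {
  fr <- 30
  set.seed(21)
  t <- seq(0, 300, by = 1 / fr)
  x <- rnorm(length(t), 0, 0.03)
  centers <- c(50, 100, 150, 200, 250)
  for (c0 in centers) x <- x + 3 * sd(x) * 4 * exp(-(t - c0)^2 / (2 * 0.4^2))
  xf <- zero_phase_lowpass(x, fr)
  cand <- detect_population_spikes(xf, fr)
  expect_equal(length(cand), length(centers))
  # steepest slope of a Gaussian rise is one sigma before the peak
  expect_lt(max(abs(sort(cand) - (centers - 0.4))), 2.5 / fr)

  expect_equal(length(detect_population_spikes(rep(0.5, 600), fr)), 0L)
})

test_that("model-spike threshold rejects sub-threshold wiggles", {
  fr <- 30
  t <- seq(0, 120, by = 1 / fr)
  # many small spike-shaped wiggles plus one large spike
  x <- numeric(length(t))
  for (c0 in seq(10, 110, by = 5)) x <- x + 0.1 * exp(-(t - c0)^2 / (2 * 0.2^2))
  x <- x + 2 * exp(-(t - 62)^2 / (2 * 0.4^2))
  xf <- zero_phase_lowpass(x, fr)
  cand <- detect_population_spikes(xf, fr)
  expect_equal(length(cand), 1L)
  expect_lt(abs(cand - (62 - 0.4)), 2.5 / fr)
})

test_that("calcium-EEG reconciliation pairs one-to-one and keeps EEG times", {
  sp <- function(t) new_spike_set(t, rep("threshold", length(t)))
  r <- reconcile_with_eeg(c(10.00, 20.00), sp(c(10.05, 30.00)))
  expect_equal(r$pis_times, 10.05)
  expect_equal(r$matched_calcium, c(TRUE, FALSE))

  expect_equal(reconcile_with_eeg(10.00, sp(10.30))$pis_times, numeric(0))

  # two calcium candidates compete for one EEG spike: nearest wins, one pair
  r3 <- reconcile_with_eeg(c(10.00, 10.10), sp(10.05))
  expect_equal(r3$pis_times, 10.05)
  expect_equal(sum(r3$matched_calcium), 1L)

  expect_warning(r4 <- reconcile_with_eeg(c(1, 2), new_spike_set()), "empty")
  expect_equal(r4$pis_times, numeric(0))
})

test_that("reconciliation match count agrees with brute-force optimal matching", {
  set.seed(22)
  for (i in 1:20) {
    ca <- sort(runif(5, 0, 30))
    ee <- sort(runif(5, 0, 30))
    r <- reconcile_with_eeg(ca, new_spike_set(ee, rep("threshold", 5)), tol = 1)
    expect_equal(length(r$pis_times), bf_max_matches(ca, ee, tol = 1))
  }
})

test_that("wavefront detection picks the two largest supra-half-max events", {
  fr <- 10
  t <- seq(0, 120, by = 1 / fr)
  x <- numeric(length(t))
  x[t >= 30 & t < 60] <- 1          # 30-s plateau
  x[t >= 90 & t < 100] <- 1         # 10-s plateau, equal height
  w <- detect_wavefronts(x, fr)
  expect_equal(w$seizure_time, 30)
  expect_equal(w$terminal_time, 90)

  # single event: seizure set, terminal absent with warning
  x2 <- numeric(length(t))
  x2[t >= 50 & t < 70] <- 1
  expect_warning(w2 <- detect_wavefronts(x2, fr), "only one event")
  expect_equal(w2$seizure_time, 50)
  expect_true(is.na(w2$terminal_time))

  # equal integrals: temporal order breaks the tie
  x3 <- numeric(length(t))
  x3[t >= 20 & t < 30] <- 1
  x3[t >= 80 & t < 90] <- 1
  w3 <- detect_wavefronts(x3, fr)
  expect_equal(w3$seizure_time, 20)
  expect_equal(w3$terminal_time, 80)
})

test_that("wavefront indexing is the first upward half-max crossing", {
  fr <- 10
  t <- seq(0, 200, by = 1 / fr)
  # plateau from ~50 to ~100, then a smaller slow bump at 150
  x <- 2 * stats::plogis(t - 50) - 2 * stats::plogis(t - 100) +
    1.5 * exp(-(t - 150)^2 / (2 * 9))
  w <- detect_wavefronts(x, fr)
  # half max ~1; the plateau's rising edge crosses it at t = 50
  expect_equal(w$seizure_time, 50, tolerance = 0.3)
  expect_true(is.finite(w$terminal_time))
  expect_lt(w$seizure_time, w$terminal_time)
  expect_equal(w$terminal_time, 150 - sqrt(2 * 9 * log(1.5 / 1)),
               tolerance = 0.5)
})

test_that("event_seeds enforces ordering invariants with warnings", {
  expect_warning(event_seeds(c(5, 20), seizure_time = 10, terminal_time = 30),
                 "at or after seizure")
  expect_warning(event_seeds(numeric(0), seizure_time = 40, terminal_time = 35),
                 "does not precede")
  s <- event_seeds(c(3, 1, 2), seizure_time = 10, terminal_time = 20,
                   provenance = c("a", "b", "c"))
  expect_equal(s$pis_times, c(1, 2, 3))
  expect_equal(s$provenance, c("b", "c", "a"))
})
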