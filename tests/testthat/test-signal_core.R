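test_that("preprocess_traces applies background, neuropil and baseline rules", {
  # two cells, 100 frames at 1 Hz; cell 2's neuropil provides the global min 40
  n <- 100
  soma <- rbind(rep(110, n), rep(200, n))
  npil <- rbind(rep(50, n), rep(40, n))
  soma[1, 51] <- 173
  rec <- calcium_recording(soma, npil, cbind(x = c(0, 10), y = c(0, 10)),
                           frame_rate = 1)
  norm <- preprocess_traces(rec)
  expect_equal(norm$background, 40)
  # corrected = (110-40) - 0.7*(50-40) = 63; constant -> dff 0
  expect_equal(norm$f0_soma[1], 63)
  expect_equal(norm$dff_soma[1, 1], 0)
  # frame 51: corrected = 133 - 7 = 126 -> dff = 126/63 - 1 = 1
  expect_equal(norm$dff_soma[1, 51], 1)
  # baseline-window mean of every valid dff trace is ~0
  expect_lt(max(abs(rowMeans(norm$dff_soma[, 1:30]))), 1e-10)
  expect_lt(max(abs(rowMeans(norm$dff_neuropil[1, 1:30, drop = FALSE]))), 1e-10)
})

test_that("preprocess_traces with zero coefficient and zero background is the plain dff", {
  n <- 60
  soma <- matrix(80, 1, n)
  npil <- matrix(runif(n, 0, 5), 1, n)
  npil[1, 7] <- 0                       # global min = 0
  rec <- calcium_recording(soma, npil, cbind(x = 0, y = 0), frame_rate = 1)
  norm <- preprocess_traces(rec, neuropil_coeff = 0)
  expect_equal(unname(norm$dff_soma[1, ]), rep(0, n))
})

test_that("preprocess_traces is invariant to a common constant shift", {
  set.seed(5)
  n <- 80
  soma <- matrix(100 + cumsum(rnorm(n)), 1, n)
  npil <- matrix(50 + runif(n), 1, n)
  rec1 <- calcium_recording(soma, npil, cbind(x = 0, y = 0), frame_rate = 1)
  rec2 <- calcium_recording(soma + 25, npil + 25, cbind(x = 0, y = 0),
                            frame_rate = 1)
  expect_equal(preprocess_traces(rec1)$dff_soma,
               preprocess_traces(rec2)$dff_soma)
})

test_that("cells with non-positive F0 are flagged invalid and excluded", {
  n <- 60
  soma <- rbind(rep(100, n), rep(10, n))   # cell 2: corrected F0 <= 0
  npil <- rbind(rep(40, n), rep(40, n))
  npil[1, 3] <- 10
  rec <- calcium_recording(soma, npil, cbind(x = c(0, 1), y = c(0, 1)),
                           frame_rate = 1)
  expect_message(norm <- preprocess_traces(rec), "non-positive somatic F0")
  expect_equal(norm$valid, c(TRUE, FALSE))
  expect_true(all(is.na(norm$dff_soma[2, ])))
})

test_that("zero_phase_lowpass preserves symmetric pulse timing and DC level", {
  fr <- 30
  t <- seq(0, 10, by = 1 / fr)
  pulse <- exp(-(t - 5)^2 / (2 * 0.2^2))
  y <- zero_phase_lowpass(pulse, fr)
  expect_lte(abs(which.max(y) - which.max(pulse)), 1)
  expect_true(attr(y, "order") %in% 3:5)

  const <- rep(2.5, 400)
  expect_equal(as.numeric(zero_phase_lowpass(const, fr)), const)
})

test_that("zero_phase_lowpass strongly attenuates a 10 Hz sinusoid", {
  fr <- 30
  t <- seq(0, 60, by = 1 / fr)
  y <- zero_phase_lowpass(sin(2 * pi * 10 * t), fr, cutoff = 1)
  expect_lt(max(abs(y[400:1400])), 1e-6)
})

test_that("zero_phase_lowpass validates its input", {
  expect_error(zero_phase_lowpass(c(1, NA, 3, rep(0, 50)), 30), "non-finite")
  expect_error(zero_phase_lowpass(rnorm(10), 30), "too short")
  expect_error(zero_phase_lowpass(rnorm(100), 30, cutoff = 20), "Nyquist")
})

test_that("positive_slope_segments isolates rises with telescoping integrals", {
  fr <- 1
  segs <- positive_slope_segments(c(0, 0.2, 0.7, 1.0, 0.8), fr)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$slope_integral, 1.0)
  # steepest first difference is the 0.2 -> 0.7 step (frames 2 -> 3)
  expect_equal(segs$index_time, 1)       # 0-based frame 1 at 1 Hz
  expect_equal(segs$peak_value, 1.0)

  expect_equal(nrow(positive_slope_segments(5:1, fr)), 0L)

  two_bumps <- c(0, 0.5, 1, 0.5, 0, 0, 0.4, 1, 0.2)
  segs2 <- positive_slope_segments(two_bumps, fr)
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$slope_integral, bf_slope_integrals(two_bumps))
})

test_that("slope integrals equal brute-force accumulation on random traces", {
  set.seed(42)
  for (i in 1:25) {
    x <- cumsum(rnorm(200))
    segs <- positive_slope_segments(x, 30)
    expect_equal(segs$slope_integral, bf_slope_integrals(x), tolerance = 1e-12)
    # telescoping identity
    expect_equal(segs$slope_integral,
                 x[segs$end_frame] - x[segs$start_frame], tolerance = 1e-12)
    expect_true(all(segs$start_frame < segs$end_frame))
    expect_true(all(segs$slope_integral >= 0))
  }
})
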