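make_noise_eeg <- function(dur = 60, fs = 500, seed = 1, sd = 1) {
  set.seed(seed)
  eeg_recording(rnorm(dur * fs, 0, sd), fs, bandpass = c(0.5, fs / 4))
}

test_that("threshold detector finds an inserted deflection and nothing else", {
  eeg <- make_noise_eeg(seed = 2)
  x <- eeg$samples
  x[15001] <- 10
  eeg <- eeg_recording(x, eeg$fs, bandpass = c(0.5, eeg$fs / 4))
  sp <- detect_eeg_spikes_threshold(eeg)
  expect_equal(length(sp$times), 1L)
  expect_equal(sp$times, 15000 / eeg$fs)
  expect_equal(sp$source, "threshold")

  # pure noise at a 10-SD threshold: nothing
  expect_equal(length(detect_eeg_spikes_threshold(make_noise_eeg(seed = 3),
                                                  k_sd = 10)$times), 0L)
})

test_that("threshold detector enforces minimum separation (larger peak wins)", {
  eeg <- make_noise_eeg(seed = 4)
  x <- eeg$samples
  x[10001] <- 10
  x[10001 + round(0.3 * eeg$fs)] <- 12
  sp <- detect_eeg_spikes_threshold(eeg_recording(x, eeg$fs, bandpass = c(0.5, eeg$fs / 4)))
  expect_equal(length(sp$times), 1L)
  expect_equal(sp$times, (10000 + round(0.3 * eeg$fs)) / eeg$fs)
})

test_that("flat EEG yields an empty set with a warning", {
  eeg <- eeg_recording(rep(0, 5000), 500, bandpass = c(0.5, 100))
  expect_warning(sp <- detect_eeg_spikes_threshold(eeg), "flat")
  expect_equal(length(sp$times), 0L)
})

test_that("welch_psd concentrates a sinusoid's power and conserves variance", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 8 * t) + 0.1 * rnorm(length(t))
  p <- welch_psd(x, fs)
  df <- p$freq[2] - p$freq[1]
  expect_equal(p$freq[which.max(p$psd)], 8, tolerance = df)
  expect_equal(sum(p$psd) * df, var(x), tolerance = 0.1)
  in_band <- sum(p$psd[p$freq >= 6 & p$freq <= 10]) * df
  expect_gt(in_band / (sum(p$psd) * df), 0.9)
})

test_that("spectral ratio keeps theta-alpha bursts and rejects gamma bursts", {
  fs <- 500
  set.seed(6)
  base <- as.numeric(stats::filter(rnorm(60 * fs), 0.99, method = "recursive"))
  base <- base / sd(base)
  tseg <- seq(0, 0.5, by = 1 / fs)
  x <- base
  x[round(20 * fs) + seq_along(tseg)] <- x[round(20 * fs) + seq_along(tseg)] +
    10 * sin(2 * pi * 10 * tseg)
  x[round(40 * fs) + seq_along(tseg)] <- x[round(40 * fs) + seq_along(tseg)] +
    10 * sin(2 * pi * 40 * tseg)
  eeg <- eeg_recording(x, fs, bandpass = c(0.5, fs / 4))
  cand <- new_spike_set(c(20.25, 40.25), rep("threshold", 2))
  kept <- spectral_ratio_filter(eeg, cand)
  expect_equal(kept$times, 20.25)
})

test_that("spectral ratio then ISI rule removes the later of close spikes", {
  fs <- 500
  set.seed(7)
  x <- rnorm(30 * fs, 0, 0.01)
  tseg <- seq(0, 0.4, by = 1 / fs)
  for (t0 in c(10, 10.5)) {
    idx <- round(t0 * fs) + seq_along(tseg)
    x[idx] <- x[idx] + 5 * sin(2 * pi * 8 * tseg)
  }
  eeg <- eeg_recording(x, fs, bandpass = c(0.5, fs / 4))
  cand <- new_spike_set(c(10.2, 10.7), rep("threshold", 2))
  kept <- spectral_ratio_filter(eeg, cand)
  expect_equal(kept$times, 10.2)
})

test_that("spectral_ratio_filter never adds spikes and warns at boundaries", {
  eeg <- make_noise_eeg(dur = 3, seed = 8)
  cand <- new_spike_set(c(0.1, 2.9), rep("threshold", 2))
  expect_warning(kept <- spectral_ratio_filter(eeg, cand), "truncated")
  expect_lte(length(kept$times), length(cand$times))
})

test_that("SWD kernel is the mean of its source segments", {
  fs <- 500
  w <- dnorm(seq(-0.5, 0.5, by = 1 / fs), sd = 0.05)
  x <- rep(0, 30 * fs)
  times <- c(5, 12, 20)
  hw <- (length(w) - 1) / 2
  for (tt in times) {
    idx <- round(tt * fs) + 1 + (-hw:hw)
    x[idx] <- x[idx] + w
  }
  eeg <- eeg_recording(x, fs, bandpass = c(0.5, fs / 4))
  k <- build_swd_kernel(eeg, times)
  expect_equal(k$waveform, w)
  expect_equal(length(k$waveform), 2 * 0.5 * fs + 1)

  # w and -w cancel
  x2 <- rep(0, 30 * fs)
  x2[round(5 * fs) + 1 + (-hw:hw)] <- w
  x2[round(20 * fs) + 1 + (-hw:hw)] <- -w
  k2 <- build_swd_kernel(eeg_recording(x2, fs, bandpass = c(0.5, fs / 4)), c(5, 20))
  expect_lt(max(abs(k2$waveform)), 1e-12)

  expect_error(build_swd_kernel(eeg, numeric(0)), "no concordant")
})

test_that("kernel averaging suppresses independent noise like 1/sqrt(N)", {
  fs <- 200
  set.seed(9)
  w <- dnorm(seq(-0.5, 0.5, by = 1 / fs), sd = 0.05)
  n_seg <- 50
  times <- seq(2, 2 + 2 * (n_seg - 1), by = 2)
  x <- rnorm((max(times) + 5) * fs, 0, 1)
  hw <- (length(w) - 1) / 2
  for (tt in times) {
    idx <- round(tt * fs) + 1 + (-hw:hw)
    x[idx] <- x[idx] + w
  }
  k <- build_swd_kernel(eeg_recording(x, fs, bandpass = c(0.5, fs / 4)), times)
  err <- k$waveform - w
  expect_lt(sd(err), 3 / sqrt(n_seg))   # noise SD 1 -> kernel error ~ 1/sqrt(N)
})

test_that("matched-kernel recovery locates an inserted waveform", {
  fs <- 500
  set.seed(10)
  x <- rnorm(200 * fs, 0, 1)
  tseg <- seq(-0.5, 0.5, by = 1 / fs)
  w <- -8 * exp(-tseg^2 / (2 * 0.03^2)) + 3 * exp(-(tseg - 0.25)^2 / (2 * 0.12^2))
  hw <- (length(w) - 1) / 2
  idx <- round(100 * fs) + 1 + (-hw:hw)
  x[idx] <- x[idx] + w
  eeg <- eeg_recording(x, fs, bandpass = c(0.5, fs / 4))
  kern <- structure(list(waveform = w, half_width = 0.5, fs = fs, n_spikes = 1),
                    class = "swd_kernel")
  out <- recover_missed_spikes(eeg, kern, new_spike_set())
  expect_equal(length(out$times), 1L)
  expect_lt(abs(out$times - 100), 0.05)
  expect_equal(out$source, "kernel_recovered")

  # already-detected spikes are not duplicated; nothing is ever removed
  existing <- new_spike_set(100, "threshold")
  out2 <- recover_missed_spikes(eeg, kern, existing)
  expect_equal(out2$times, existing$times)

  # waveform below the 5-SD correlation criterion is not recovered
  x3 <- rnorm(200 * fs, 0, 1)
  x3[idx] <- x3[idx] + 0.05 * w
  out3 <- recover_missed_spikes(eeg_recording(x3, fs, bandpass = c(0.5, fs / 4)), kern, new_spike_set())
  expect_equal(length(out3$times), 0L)
})

test_that("spike sets stay sorted and within bounds through the EEG chain", {
  sim <- cached_sim("nf", noise_free_cfg())
  sp <- detect_eeg_spikes_threshold(sim$eeg)
  sp2 <- spectral_ratio_filter(sim$eeg, sp)
  expect_true(!is.unsorted(sp$times))
  expect_true(!is.unsorted(sp2$times))
  expect_true(all(sp2$times %in% sp$times))
  expect_true(all(sp$times >= 0 &
                    sp$times <= length(sim$eeg$samples) / sim$eeg$fs))
})
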