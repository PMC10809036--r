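#' Welch power spectral density
#'
#' Averaged modified periodogram (Welch's method) with a Hann taper. Used to
#' compute spectral band-power ratios around candidate EEG spikes; the density
#' is scaled so that `sum(psd) * df` approximates the signal variance
#' (one-sided density).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default `fs / 2`, i.e. 0.5 s).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_len = round(fs / 2), overlap = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  u <- sum(w^2)
  nfft <- seg_len
  acc <- numeric(floor(nfft / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[seq_along(acc)]
  }
  psd <- acc / (length(starts) * u * fs)
  ## one-sided: double everything except DC (and Nyquist when nfft even)
  two <- rep(2, length(psd))
  two[1L] <- 1
  if (nfft %% 2 == 0) two[length(two)] <- 1
  list(freq = (seq_along(psd) - 1L) * fs / nfft, psd = psd * two)
}

band_power <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq <= hi
  df <- psd$freq[2L] - psd$freq[1L]
  sum(psd$psd[sel]) * df
}

#' Construct an EEG spike set
#'
#' Sorted spike peak times with a per-spike source tag (`"threshold"` or
#' `"kernel_recovered"`).
#'
#' @param times spike peak times, seconds.
#' @param source character vector parallel to `times`.
#' @return list of class `eeg_spike_set`.
#' @export
new_spike_set <- function(times = numeric(0), source = character(0)) {
  o <- order(times)
  structure(list(times = times[o], source = source[o]), class = "eeg_spike_set")
}

#' @export
print.eeg_spike_set <- function(x, ...) {
  cat(sprintf("<eeg_spike_set> %d spikes (%d threshold, %d kernel_recovered)\n",
              length(x$times), sum(x$source == "threshold"),
              sum(x$source == "kernel_recovered")))
  invisible(x)
}

## Greedy amplitude-ordered peak picking with a minimum separation: returns
## sample indices of local |score| maxima at least min_sep_samples apart.
pick_separated_peaks <- function(score, candidates, min_sep_samples) {
  if (length(candidates) == 0L) return(integer(0))
  ord <- candidates[order(score[candidates], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(accepted - i) >= min_sep_samples)) accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Threshold detection of EEG spike candidates
#'
#' Amplitude-threshold candidate detector: samples where the absolute voltage
#' exceeds `k_sd` robust standard deviations (median absolute deviation scaled
#' by 1.4826) of the whole trace are grouped into peaks indexed at the local
#' absolute-value maximum, with a minimum separation between retained peaks
#' (larger peak wins).
#'
#' @param eeg an [eeg_recording()].
#' @param k_sd threshold multiplier (default 4.5).
#' @param min_separation minimum separation between peaks, seconds (default 0.7).
#' @return An `eeg_spike_set` (sorted times, source `"threshold"`).
#' @export
detect_eeg_spikes_threshold <- function(eeg, k_sd = 4.5, min_separation = 0.7) {
  stopifnot(inherits(eeg, "eeg_recording"))
  x <- eeg$samples
  rsd <- stats::mad(x)
  if (rsd == 0) {
    warning("flat EEG signal (robust SD = 0); no spikes detected")
    return(new_spike_set())
  }
  thr <- k_sd * rsd
  cand <- which(abs(x) > thr)
  idx <- pick_separated_peaks(abs(x), cand, round(min_separation * eeg$fs))
  new_spike_set(eeg$t0 + (idx - 1L) / eeg$fs,
                rep("threshold", length(idx)))
}

#' Spectral-ratio exclusion of EEG spike candidates
#'
#' Spike-wave discharges in this seizure model carry strong theta--alpha
#' (3--15 Hz) power relative to the low-gamma (20--55 Hz) power that follows
#' them. For each candidate, a Welch PSD is computed over a 1-s window
#' starting 0.25 s before the spike peak (theta--alpha band) and over the
#' subsequent 1-s window (low-gamma band); candidates whose band-power ratio
#' falls below `ratio_min` are removed, then spikes closer than `isi_min` to
#' their retained predecessor are removed (the earlier spike is kept).
#' Windows extending past the record are truncated with a warning.
#'
#' @param eeg an [eeg_recording()].
#' @param spikes an `eeg_spike_set` of candidates.
#' @param ratio_min minimum 3--15 Hz / 20--55 Hz power ratio (default 20).
#' @param isi_min minimum inter-spike interval in seconds (default 0.7).
#' @return Filtered `eeg_spike_set` (never adds spikes).
#' @export
spectral_ratio_filter <- function(eeg, spikes, ratio_min = 20, isi_min = 0.7) {
  stopifnot(inherits(eeg, "eeg_recording"), inherits(spikes, "eeg_spike_set"))
  if (length(spikes$times) == 0L) return(spikes)
  n <- length(eeg$samples)
  fs <- eeg$fs
  keep <- logical(length(spikes$times))
  truncated <- FALSE
  for (k in seq_along(spikes$times)) {
    i0 <- round((spikes$times[k] - eeg$t0 - 0.25) * fs) + 1L
    iA <- c(i0, i0 + round(fs) - 1L)          # spike window
    iB <- iA + round(fs)                      # subsequent window
    clampA <- pmin(pmax(iA, 1L), n)
    clampB <- pmin(pmax(iB, 1L), n)
    if (any(clampA != iA) || any(clampB != iB)) truncated <- TRUE
    segA <- eeg$samples[clampA[1L]:clampA[2L]]
    segB <- eeg$samples[clampB[1L]:clampB[2L]]
    p_theta <- band_power(welch_psd(segA, fs), 3, 15)
    p_gamma <- band_power(welch_psd(segB, fs), 20, 55)
    keep[k] <- is.finite(p_theta / p_gamma) && p_theta / p_gamma >= ratio_min
  }
  if (truncated) warning("spectral_ratio_filter: window(s) truncated at record boundary")
  tt <- spikes$times[keep]
  ss <- spikes$source[keep]
  if (length(tt) > 1L) {
    keep2 <- c(TRUE, diff(tt) >= isi_min)
    ## sequential: an ISI is measured against the last *retained* spike
    last <- tt[1L]
    for (k in seq_along(tt)[-1L]) {
      keep2[k] <- (tt[k] - last) >= isi_min
      if (keep2[k]) last <- tt[k]
    }
    tt <- tt[keep2]; ss <- ss[keep2]
  }
  new_spike_set(tt, ss)
}

#' Build a spike-wave-discharge kernel
#'
#' Mean of EEG segments `[t - half_width, t + half_width]` across the
#' calcium--EEG concordant pre-ictal spikes, centered on the spike peak.
#'
#' @param eeg an [eeg_recording()].
#' @param concordant_times spike peak times in seconds (>= 1 required).
#' @param half_width kernel half width in seconds (default 0.5).
#' @return list of class `swd_kernel`: `waveform`, `half_width`, `fs`.
#' @export
build_swd_kernel <- function(eeg, concordant_times, half_width = 0.5) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (length(concordant_times) < 1L) {
    stop("build_swd_kernel: no concordant spikes; kernel-recovery stage skipped")
  }
  hw <- round(half_width * eeg$fs)
  n <- length(eeg$samples)
  centers <- round((concordant_times - eeg$t0) * eeg$fs) + 1L
  ok <- centers - hw >= 1L & centers + hw <= n
  if (!any(ok)) stop("build_swd_kernel: all kernel windows fall outside the record")
  segs <- vapply(centers[ok], function(c0) eeg$samples[(c0 - hw):(c0 + hw)],
                 numeric(2L * hw + 1L))
  structure(list(waveform = rowMeans(segs), half_width = half_width,
                 fs = eeg$fs, n_spikes = sum(ok)),
            class = "swd_kernel")
}

#' Recover missed spikes by matched-kernel correlation
#'
#' Cross-correlates the EEG with the SWD kernel (lag-corrected so maxima align
#' with the kernel center), finds local maxima at least 5 standard deviations
#' above the correlation trace's baseline mean and at least `min_separation`
#' apart, and appends those not already within `dedup_tol` of an existing
#' spike, tagged `"kernel_recovered"`. Never removes spikes.
#'
#' @param eeg an [eeg_recording()].
#' @param kernel an `swd_kernel` from [build_swd_kernel()].
#' @param existing an `eeg_spike_set` of already-detected spikes.
#' @param k_sd threshold multiplier above the correlation baseline (default 5).
#' @param min_separation minimum separation between recovered maxima, seconds
#'   (default 1).
#' @param dedup_tol distance below which a recovered time is considered a
#'   duplicate of an existing spike, seconds (default 0.5).
#' @return Augmented `eeg_spike_set`.
#' @export
recover_missed_spikes <- function(eeg, kernel, existing, k_sd = 5,
                                  min_separation = 1, dedup_tol = 0.5) {
  stopifnot(inherits(eeg, "eeg_recording"), inherits(kernel, "swd_kernel"))
  x <- eeg$samples
  k <- kernel$waveform
  n <- length(x)
  m <- length(k)
  ## cross-correlation via FFT; value at sample i = sum_j x[i + j - center] k[j]
  nfft <- stats::nextn(n + m, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  K <- fft(c(k, rep(0, nfft - m)))
  full <- Re(fft(X * Conj(K), inverse = TRUE)) / nfft   # lag 0 at index 1
  center <- (m - 1L) %/% 2L
  ## corr[i] = sum_j x[i - center - 1 + j] k[j]: kernel centered on sample i
  corr <- full[((seq_len(n) - 1L - center) %% nfft) + 1L]
  thr <- mean(corr) + k_sd * stats::sd(corr)
  is_max <- c(FALSE, diff(sign(diff(corr))) < 0, FALSE)
  cand <- which(is_max & corr >= thr)
  idx <- pick_separated_peaks(corr, cand, round(min_separation * eeg$fs))
  times <- eeg$t0 + (idx - 1L) / eeg$fs
  new <- times[vapply(times, function(t) {
    length(existing$times) == 0L || min(abs(existing$times - t)) > dedup_tol
  }, logical(1L))]
  new_spike_set(c(existing$times, new),
                c(existing$source, rep("kernel_recovered", length(new))))
}
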