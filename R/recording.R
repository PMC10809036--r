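#' Calcium recording container
#'
#' Bundles raw somatic and neuropil fluorescence traces (Suite2p convention:
#' one row per ROI, one column per frame), ROI centroid positions in
#' micrometers, the imaging frame rate, and the offset of frame 0 relative to
#' the shared EEG clock. Frame `i` (0-based) maps to time
#' `t0_offset + i / frame_rate` seconds.
#'
#' @param soma_raw numeric matrix, cells x frames, somatic fluorescence (a.u.).
#' @param neuropil_raw numeric matrix, same shape, surrounding-neuropil
#'   fluorescence (a.u.).
#' @param positions numeric matrix or data.frame with columns `x`, `y`
#'   (micrometers), one row per cell.
#' @param frame_rate imaging frame rate in Hz (resonant scanning ~30 Hz).
#' @param t0_offset time of frame 0 on the EEG clock, seconds. Default 0
#'   (imaging triggered by the EEG system's TTL pulse).
#'
#' @return An object of class `calcium_recording`.
#' @export
calcium_recording <- function(soma_raw, neuropil_raw, positions, frame_rate,
                              t0_offset = 0) {
  soma_raw <- as.matrix(soma_raw)
  neuropil_raw <- as.matrix(neuropil_raw)
  if (!all(dim(soma_raw) == dim(neuropil_raw))) {
    stop("soma_raw and neuropil_raw must have identical dimensions")
  }
  positions <- as.matrix(positions)[, 1:2, drop = FALSE]
  colnames(positions) <- c("x", "y")
  if (nrow(positions) != nrow(soma_raw)) {
    stop("positions must have one row per cell")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_rate must be a single positive number")
  }
  structure(
    list(soma_raw = soma_raw, neuropil_raw = neuropil_raw,
         positions = positions, frame_rate = frame_rate,
         t0_offset = t0_offset),
    class = "calcium_recording"
  )
}

#' @export
print.calcium_recording <- function(x, ...) {
  cat(sprintf("<calcium_recording> %d cells x %d frames @ %.3g Hz (%.1f s), t0 = %g s\n",
              nrow(x$soma_raw), ncol(x$soma_raw), x$frame_rate,
              ncol(x$soma_raw) / x$frame_rate, x$t0_offset))
  invisible(x)
}

#' Frame times of a calcium recording
#'
#' @param rec a [calcium_recording()].
#' @return numeric vector of frame times in seconds on the EEG clock.
#' @export
frame_times <- function(rec) {
  rec$t0_offset + (seq_len(ncol(rec$soma_raw)) - 1L) / rec$frame_rate
}

#' EEG recording container
#'
#' Single-channel EEG time-locked to imaging start. The acquisition bandpass
#' (0.5--300 Hz here) is carried as metadata; samples are assumed already
#' band-limited by the hardware.
#'
#' @param samples numeric vector of voltages (or a.u.).
#' @param fs sampling rate in Hz (nominal 2000).
#' @param bandpass length-2 numeric, acquisition bandpass edges in Hz.
#' @param t0 time of sample 1 in seconds (0 at the imaging trigger).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, bandpass = c(0.5, 300), t0 = 0) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("EEG samples must be finite")
  if (fs <= 2 * max(bandpass)) {
    stop("EEG sampling rate must exceed twice the upper bandpass edge")
  }
  structure(list(samples = samples, fs = fs, bandpass = bandpass, t0 = t0),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples @ %g Hz (%.1f s), bandpass %g-%g Hz\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$bandpass[1], x$bandpass[2]))
  invisible(x)
}

eeg_times <- function(eeg) eeg$t0 + (seq_along(eeg$samples) - 1L) / eeg$fs
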