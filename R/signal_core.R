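#' Normalize raw traces to \eqn{\Delta F/F_0}
#'
#' Background subtraction, neuropil correction and baseline normalization.
#' The background `b` is a single scalar per recording: the global minimum of
#' all neuropil samples, a proxy for the non-biological offset. The clean
#' somatic signal is `(soma - b) - neuropil_coeff * (neuropil - b)`; this also
#' compensates slow photobleaching shared with the neuropil. Each corrected
#' trace is then normalized as `corrected / F0 - 1` with `F0` the mean of the
#' corrected trace over the first `baseline_window` seconds, so every
#' \eqn{\Delta F/F_0} trace has (approximately) zero mean over that window.
#' Neuropil traces are normalized the same way (without soma subtraction).
#'
#' Cells whose baseline `F0` is not positive cannot be normalized; they are
#' flagged invalid (`valid = FALSE`), their \eqn{\Delta F/F_0} set to `NA`, and
#' downstream detectors skip them.
#'
#' @param rec a [calcium_recording()].
#' @param neuropil_coeff fraction of the neuropil signal subtracted from the
#'   soma (default 0.7).
#' @param baseline_window seconds of recording start used as baseline
#'   (default 30).
#'
#' @return A list of class `normalized_traces`: `dff_soma`, `dff_neuropil`
#'   (cells x frames), `mean_neuropil` (per-frame mean across valid cells),
#'   `valid` (logical per cell), `background`, `f0_soma`, `f0_neuropil`,
#'   `frame_rate`, `t0_offset`.
#' @export
preprocess_traces <- function(rec, neuropil_coeff = 0.7, baseline_window = 30) {
  stopifnot(inherits(rec, "calcium_recording"))
  if (neuropil_coeff < 0 || neuropil_coeff >= 1) {
    stop("neuropil_coeff must be in [0, 1)")
  }
  n_frames <- ncol(rec$soma_raw)
  n_base <- floor(baseline_window * rec$frame_rate)
  if (n_frames <= n_base) stop("recording shorter than the baseline window")

  b <- min(rec$neuropil_raw)
  soma_c <- (rec$soma_raw - b) - neuropil_coeff * (rec$neuropil_raw - b)
  npil_c <- rec$neuropil_raw - b

  base_idx <- seq_len(n_base)
  f0_s <- rowMeans(soma_c[, base_idx, drop = FALSE])
  f0_n <- rowMeans(npil_c[, base_idx, drop = FALSE])

  ## somatic and neuropil baselines are validated separately: a neuropil F0 of
  ## zero (the cell sitting at the global background minimum) only invalidates
  ## that cell's neuropil trace, not its somatic detection
  valid <- f0_s > 0
  valid_npil <- f0_n > 0
  if (!all(valid)) {
    message(sprintf("preprocess_traces: %d cell(s) with non-positive somatic F0 flagged invalid",
                    sum(!valid)))
  }
  dff_s <- soma_c / f0_s - 1
  dff_n <- npil_c / f0_n - 1
  dff_s[!valid, ] <- NA_real_
  dff_n[!valid_npil, ] <- NA_real_

  mean_np <- if (any(valid_npil)) {
    colMeans(dff_n[valid_npil, , drop = FALSE])
  } else {
    rep(NA_real_, n_frames)
  }

  structure(
    list(dff_soma = dff_s, dff_neuropil = dff_n, mean_neuropil = mean_np,
         valid = valid, valid_npil = valid_npil,
         background = b, f0_soma = f0_s, f0_neuropil = f0_n,
         frame_rate = rec$frame_rate, t0_offset = rec$t0_offset,
         neuropil_coeff = neuropil_coeff, baseline_window = baseline_window),
    class = "normalized_traces"
  )
}

## Digital Butterworth low-pass design via the bilinear transform.
## Returns list(b, a) with sum(b)/sum(a) = 1 (unit DC gain).
butter_lowpass <- function(order, cutoff, fs) {
  if (cutoff <= 0 || cutoff >= fs / 2) stop("cutoff must be in (0, fs/2)")
  ## analog prototype poles on the unit circle, scaled by the prewarped cutoff
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  warped <- 4 * tan(pi * cutoff / fs)         # bilinear with fs' = 2
  s_poles <- warped * exp(1i * theta)
  z_poles <- (4 + s_poles) / (4 - s_poles)
  a <- Re(poly_from_roots(z_poles))
  b <- choose(order, 0:order)                  # (1 + z^-1)^order: zeros at -1
  b <- b * (sum(a) / sum(b))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0i) - c(0i, p * ri)
  p
}

## Direct-form IIR filter using C-level stats::filter for both the MA and the
## recursive part. Zero initial conditions (callers pad the signal).
iir_filter <- function(b, a, x) {
  v <- stats::filter(c(rep(0, length(b) - 1L), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[-seq_len(length(b) - 1L)]
  if (length(a) > 1L) {
    y <- stats::filter(v, -a[-1L], method = "recursive")
    as.numeric(y)
  } else {
    v
  }
}

## Forward-backward application with odd-reflection edge padding. The first
## padded sample's level is subtracted before each pass (DC gain is 1), so the
## zero-initial-state startup transient scales with local signal variation,
## not the absolute signal level.
filtfilt_butter <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  xp <- c(pre, x, post)
  off <- xp[1L]
  y <- iir_filter(b, a, xp - off) + off
  yr <- rev(y)
  off2 <- yr[1L]
  y <- rev(iir_filter(b, a, yr - off2) + off2)
  y[seq(padlen + 1L, padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Double-reverse (forward-then-backward) application of a Butterworth
#' low-pass filter, which doubles the magnitude roll-off and cancels the phase
#' shift, so event times on the filtered trace are not displaced. The order is
#' chosen adaptively: order 5 is attempted first and decremented down to 3 if
#' the output contains non-finite values or its energy exceeds the input's by
#' more than 1% (numerical instability at low normalized cutoffs).
#'
#' @param trace numeric vector.
#' @param frame_rate sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz (default 1).
#' @param order_range integer range of Butterworth orders tried, high to low
#'   (default `c(3, 5)`).
#' @return Filtered vector, same length as input, with attribute `"order"`
#'   recording the order actually used.
#' @export
zero_phase_lowpass <- function(trace, frame_rate, cutoff = 1,
                               order_range = c(3, 5)) {
  if (any(!is.finite(trace))) stop("trace contains non-finite samples")
  if (cutoff >= frame_rate / 2) stop("cutoff must be below the Nyquist rate")
  orders <- seq(max(order_range), min(order_range))
  if (length(trace) <= 3 * max(orders)) stop("trace too short to filter")
  ## pad long enough for start-up transients of the slow low-pass poles
  padlen <- max(3L * (max(orders) + 1L), ceiling(3 * frame_rate / cutoff))
  e_in <- sum(trace^2)
  for (ord in orders) {
    ba <- butter_lowpass(ord, cutoff, frame_rate)
    y <- filtfilt_butter(ba$b, ba$a, trace, padlen)
    if (all(is.finite(y)) && (e_in == 0 || sum(y^2) <= 1.01 * e_in)) {
      attr(y, "order") <- ord
      return(y)
    }
  }
  stop("zero_phase_lowpass: filter unstable at all orders in order_range")
}

#' Positive-slope segments and the slope-integral feature
#'
#' Isolates maximal runs of consecutive frames with strictly positive first
#' difference and computes, for each run, the slope-integral feature: the
#' integral of the first derivative over the run, which telescopes to the net
#' rise `trace[end] - trace[start]`. The feature jointly captures slope
#' steepness, peak height and rise duration, which separates genuine calcium
#' events from brief noise fluctuations of similar peak slope. Each segment is
#' indexed at its point of steepest slope (largest first difference; the time
#' assigned is the earlier frame of that difference).
#'
#' @param filtered_trace numeric vector (callers filter first; see
#'   [zero_phase_lowpass()]).
#' @param frame_rate sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return A data.frame with columns `start_frame`, `end_frame` (1-based,
#'   inclusive), `slope_integral` (net rise, \eqn{\Delta F/F_0} units),
#'   `index_time` (seconds), `peak_value` (trace at `end_frame`),
#'   `start_value`. Zero rows when the trace never rises.
#' @export
positive_slope_segments <- function(filtered_trace, frame_rate, t0 = 0) {
  x <- as.numeric(filtered_trace)
  n <- length(x)
  if (n < 2L) stop("trace must have at least 2 samples")
  d <- diff(x)
  pos <- d > 0
  if (!any(pos)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      slope_integral = numeric(0), index_time = numeric(0),
                      peak_value = numeric(0), start_value = numeric(0)))
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  seg_start <- starts[keep]           # index into d: run covers frames s..e+1
  seg_end <- ends[keep]
  idx <- mapply(function(s, e) s + which.max(d[s:e]) - 1L, seg_start, seg_end)
  data.frame(
    start_frame = seg_start,
    end_frame = seg_end + 1L,
    slope_integral = x[seg_end + 1L] - x[seg_start],
    index_time = t0 + (idx - 1L) / frame_rate,
    peak_value = x[seg_end + 1L],
    start_value = x[seg_start]
  )
}
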