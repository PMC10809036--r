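#' Model-spike integral
#'
#' Area of the Gaussian model spike used to threshold candidate population
#' calcium events: peak height equal to the trace standard deviation and
#' `sigma = 0.33` s (so the +/- 1.5 sigma width is ~1 s), representative of a
#' typical spike weight under normal physiologic conditions.
#'
#' @param trace_sd standard deviation of the (filtered) trace,
#'   \eqn{\Delta F/F_0}.
#' @param sigma Gaussian standard deviation in seconds (default 0.33).
#' @return Model spike area, \eqn{\Delta F/F_0 \cdot s}:
#'   `trace_sd * sigma * sqrt(2*pi)`.
#' @export
model_spike_integral <- function(trace_sd, sigma = 0.33) {
  stopifnot(trace_sd >= 0)
  trace_sd * sigma * sqrt(2 * pi)
}

## Integral of (trace - start value) over the event period: from the rising
## segment's start until the trace falls back below the start value or the
## next rising segment begins, whichever is first. Units: trace units * s.
event_period_integral <- function(trace, segments, frame_rate) {
  n <- length(trace)
  vapply(seq_len(nrow(segments)), function(k) {
    s <- segments$start_frame[k]
    v0 <- trace[s]
    stop_at <- if (k < nrow(segments)) segments$start_frame[k + 1L] - 1L else n
    run <- trace[s:stop_at] - v0
    below <- which(run < 0)
    if (length(below) > 0L) run <- run[seq_len(below[1L] - 1L)]
    sum(run) / frame_rate
  }, numeric(1L))
}

#' Detect population calcium spikes
#'
#' Candidate pre-ictal spikes on the population-mean neuropil
#' \eqn{\Delta F/F_0} trace (already low-pass filtered): positive-slope
#' segments are ranked by the slope-integral feature and the top
#' `top_frac` retained; each retained segment's event-period integral (trace
#' minus its value at segment start, integrated until the trace returns to
#' that level) must reach the model-spike integral
#' ([model_spike_integral()] at the trace's standard deviation). Any segment
#' already meeting the model-spike threshold is retained regardless of rank:
#' the rank cut is a computational triage aimed at noise-dominated segment
#' populations and would otherwise discard true events on near-noise-free
#' traces. Survivors are indexed at their point of steepest slope.
#'
#' @param mean_neuropil_filtered filtered population-mean neuropil trace.
#' @param frame_rate Hz.
#' @param t0 time of the first sample, seconds.
#' @param top_frac fraction of segments retained by rank (default 0.15).
#' @param sigma model-spike Gaussian SD, seconds (default 0.33).
#' @param trace_sd trace SD used for the model spike; defaults to
#'   `sd(mean_neuropil_filtered)`.
#' @return numeric vector of candidate times (steepest-slope points), sorted.
#' @export
detect_population_spikes <- function(mean_neuropil_filtered, frame_rate,
                                     t0 = 0, top_frac = 0.15, sigma = 0.33,
                                     trace_sd = NULL) {
  x <- as.numeric(mean_neuropil_filtered)
  segs <- positive_slope_segments(x, frame_rate, t0)
  if (nrow(segs) == 0L) return(numeric(0))
  if (is.null(trace_sd)) trace_sd <- stats::sd(x)
  thr <- model_spike_integral(trace_sd, sigma)
  integrals <- event_period_integral(x, segs, frame_rate)
  n_top <- ceiling(top_frac * nrow(segs))
  by_rank <- rank(-segs$slope_integral, ties.method = "min") <= n_top
  passes_model <- integrals >= thr
  ## candidates: top-frac by rank, with a degenerate-regime floor keeping any
  ## segment that already meets the physiologic model-spike weight (on traces
  ## with few segments the rank cut would discard true events); the model
  ## threshold is then applied to all candidates
  keep <- (by_rank | passes_model) & passes_model
  sort(segs$index_time[keep])
}

#' Reconcile calcium spike candidates with EEG spikes
#'
#' Globally one-to-one nearest pairing of calcium candidates and EEG spikes
#' (greedy by ascending time difference) within `tol` seconds; each pair
#' contributes the EEG time, the least variable feature of the spike-wave
#' discharge, as the pre-ictal spike time. Unpaired calcium candidates are
#' dropped.
#'
#' @param calcium_times sorted candidate times from
#'   [detect_population_spikes()].
#' @param eeg_spikes an `eeg_spike_set`.
#' @param tol pairing tolerance, seconds (default 0.2).
#' @return list: `pis_times` (EEG times of concordant pairs, sorted),
#'   `matched_calcium` (logical per calcium candidate), `matched_eeg`
#'   (logical per EEG spike).
#' @export
reconcile_with_eeg <- function(calcium_times, eeg_spikes, tol = 0.2) {
  et <- eeg_spikes$times
  if (length(et) == 0L) {
    warning("reconcile_with_eeg: empty EEG spike set; no pre-ictal spikes")
    return(list(pis_times = numeric(0),
                matched_calcium = rep(FALSE, length(calcium_times)),
                matched_eeg = logical(0)))
  }
  pairs <- expand.grid(ci = seq_along(calcium_times), ei = seq_along(et))
  pairs$d <- abs(calcium_times[pairs$ci] - et[pairs$ei])
  pairs <- pairs[pairs$d <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_c <- rep(FALSE, length(calcium_times))
  used_e <- rep(FALSE, length(et))
  for (r in seq_len(nrow(pairs))) {
    ci <- pairs$ci[r]; ei <- pairs$ei[r]
    if (!used_c[ci] && !used_e[ei]) {
      used_c[ci] <- TRUE
      used_e[ei] <- TRUE
    }
  }
  list(pis_times = sort(et[used_e]), matched_calcium = used_c,
       matched_eeg = used_e)
}

#' Detect seizure and terminal-wave onsets on the population trace
#'
#' The filtered population-mean neuropil trace is thresholded at half its
#' global maximum; the trace integral is computed over every contiguous
#' supra-half-max interval and the two with the largest integrals are taken as
#' the seizure (earlier) and the terminal spreading wave (later), each indexed
#' at the interval's first upward half-max crossing. Ties in integral are
#' broken by temporal order. With fewer than two supra-half-max intervals
#' (e.g. a fatal seizure truncating the recording before the terminal wave),
#' whatever exists is returned and the missing event flagged by a warning.
#'
#' @param mean_neuropil_filtered filtered population-mean neuropil trace.
#' @param frame_rate Hz.
#' @param t0 time of the first sample, seconds.
#' @return list: `seizure_time`, `terminal_time` (seconds; `NA` when absent),
#'   `intervals` (data.frame of all supra-half-max intervals with onsets and
#'   integrals), `half_max`.
#' @export
detect_wavefronts <- function(mean_neuropil_filtered, frame_rate, t0 = 0) {
  x <- as.numeric(mean_neuropil_filtered)
  half_max <- 0.5 * max(x)
  above <- x >= half_max
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  if (length(starts) == 0L) {
    warning("detect_wavefronts: no supra-half-max interval found")
    return(list(seizure_time = NA_real_, terminal_time = NA_real_,
                intervals = data.frame(onset = numeric(0), integral = numeric(0)),
                half_max = half_max))
  }
  integral <- mapply(function(s, e) sum(x[s:e]) / frame_rate, starts, ends)
  onset <- t0 + (starts - 1L) / frame_rate
  intervals <- data.frame(onset = onset, start_frame = starts,
                          end_frame = ends, integral = integral)
  ord <- order(-intervals$integral, intervals$onset)
  top2 <- sort(intervals$onset[ord[seq_len(min(2L, nrow(intervals)))]])
  seiz <- top2[1L]
  term <- if (length(top2) >= 2L) top2[2L] else NA_real_
  if (is.na(term)) {
    warning("detect_wavefronts: only one event found; terminal wave absent (truncated recording?)")
  }
  list(seizure_time = seiz, terminal_time = term, intervals = intervals,
       half_max = half_max)
}

#' Assemble population-level event seeds
#'
#' Convenience container for the seed times feeding per-cell recruitment
#' detection. Enforces the ordering invariants with warnings (never a silent
#' drop): all pre-ictal spike times should precede the seizure onset, and the
#' seizure onset the terminal-wave onset.
#'
#' @param pis_times sorted pre-ictal spike times with a `provenance` attribute
#'   or vector (`"concordant"` / `"kernel_recovered"`).
#' @param seizure_time seizure wavefront seed time or `NA`.
#' @param terminal_time terminal spreading wave seed time or `NA`.
#' @param provenance character vector parallel to `pis_times`.
#' @return list of class `event_seeds`.
#' @export
event_seeds <- function(pis_times, seizure_time = NA_real_,
                        terminal_time = NA_real_,
                        provenance = rep("concordant", length(pis_times))) {
  o <- order(pis_times)
  pis_times <- pis_times[o]
  provenance <- provenance[o]
  if (!is.na(seizure_time) && !is.na(terminal_time) &&
      seizure_time >= terminal_time) {
    warning("event_seeds: seizure time does not precede terminal time")
  }
  if (!is.na(seizure_time) && any(pis_times >= seizure_time)) {
    warning("event_seeds: pre-ictal spike time(s) at or after seizure onset")
  }
  structure(list(pis_times = pis_times, provenance = provenance,
                 seizure_time = seizure_time, terminal_time = terminal_time),
            class = "event_seeds")
}

#' @export
print.event_seeds <- function(x, ...) {
  cat(sprintf("<event_seeds> %d pre-ictal spikes (%d kernel-recovered); seizure %s s; terminal %s s\n",
              length(x$pis_times), sum(x$provenance == "kernel_recovered"),
              format(x$seizure_time), format(x$terminal_time)))
  invisible(x)
}
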