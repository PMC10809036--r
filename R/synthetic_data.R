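#' Synthetic recording configuration
#'
#' Parameters of the synthetic paired calcium + EEG recording generator. The
#' defaults describe a chemoconvulsant-seizure recording: sporadic pre-ictal
#' spikes at ~3/min with 80% per-cell participation, a sentinel spike 2--4 s
#' before ictal invasion, a fast planar seizure wavefront (421 um/s) with a
#' sustained plateau, and a slow terminal spreading wave (68 um/s) after the
#' plateau decays, imaged at 30 Hz over a 400-um field with a 2-kHz EEG
#' carrying biphasic spike-wave discharges and an ictal rhythmic discharge.
#' Indicator kinetics default to a jYCaMP1s-like half-decay of 1.4 s
#' (jRGECO1a-like recordings use ~0.4 s).
#'
#' @param n_cells number of cells (default 30).
#' @param duration recording length, seconds (default 260).
#' @param frame_rate imaging rate, Hz (default 30).
#' @param eeg_fs EEG sampling rate, Hz (default 2000).
#' @param field_um square imaging field side, micrometers (default 400).
#' @param pis_rate pre-ictal spike rate, events/min (default 3).
#' @param pis_window seconds (start, end) within which population spikes are
#'   planted; default `c(35, seizure_onset - 6)` (after the 30-s baseline,
#'   clear of the sentinel zone), or `c(35, duration - 10)` without a seizure.
#' @param pis_participation per-cell per-event recruitment probability
#'   (default 0.8).
#' @param pis_jitter per-cell timing jitter SD, seconds (default 0.05).
#' @param pis_min_gap minimum spacing between population spikes, seconds
#'   (default 4).
#' @param pis_amp_range per-cell somatic spike amplitude range,
#'   \eqn{\Delta F/F_0} (default `c(1.2, 2)`; amplitudes above the 1
#'   \eqn{\Delta F/F_0} SNR peak-prominence criterion).
#' @param sentinel plant a sentinel spike before the seizure (default TRUE).
#' @param seizure plant a seizure (default TRUE).
#' @param seizure_onset ictal invasion start, seconds (default 190).
#' @param seizure_velocity,seizure_angle planar wavefront speed (um/s,
#'   default 421) and direction (degrees CCW from +x, default 0).
#' @param plateau_amp ictal plateau amplitude, \eqn{\Delta F/F_0} (default 3).
#' @param plateau_dur plateau duration, seconds (default 20).
#' @param terminal plant a terminal spreading wave (default TRUE).
#' @param terminal_onset terminal wave start, seconds (default 225).
#' @param terminal_velocity,terminal_angle terminal wave speed (um/s, default
#'   68) and direction (degrees, default 152).
#' @param terminal_amp terminal transient amplitude, \eqn{\Delta F/F_0}
#'   (default 2.5; spreading-depolarization transients are large and long).
#' @param half_decay indicator half-decay time, seconds (default 1.4).
#' @param rise_tau transient rise time constant, seconds (default 0.1).
#' @param noise_sd white noise SD per cell, \eqn{\Delta F/F_0} (default 0.1).
#' @param shared_noise_sd noise common to all cells and the neuropil
#'   (default `noise_sd / 5`).
#' @param drift_amp slow baseline drift amplitude (default 0.02).
#' @param neuropil_coupling fraction of the population signal carried by each
#'   neuropil trace (default 0.8).
#' @param swd_amp EEG spike-wave discharge amplitude in units of the EEG noise
#'   SD (default 10).
#' @param eeg_noise_sd EEG background noise SD, a.u. (default 1).
#' @param rng_seed integer seed (default 1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 30, duration = 260, frame_rate = 30,
                       eeg_fs = 2000, field_um = 400, pis_rate = 3,
                       pis_window = NULL, pis_participation = 0.8,
                       pis_jitter = 0.05, pis_min_gap = 4,
                       pis_amp_range = c(1.2, 2), sentinel = TRUE,
                       seizure = TRUE, seizure_onset = 190,
                       seizure_velocity = 421, seizure_angle = 0,
                       plateau_amp = 3, plateau_dur = 20, terminal = TRUE,
                       terminal_onset = 225, terminal_velocity = 68,
                       terminal_angle = 152, terminal_amp = 2.5,
                       half_decay = 1.4, rise_tau = 0.1, noise_sd = 0.1,
                       shared_noise_sd = noise_sd / 5, drift_amp = 0.02,
                       neuropil_coupling = 0.8, swd_amp = 10,
                       eeg_noise_sd = 1, rng_seed = 1) {
  if (!seizure) {
    sentinel <- FALSE
    terminal <- FALSE
  }
  if (is.null(pis_window)) {
    pis_window <- c(35, if (seizure) seizure_onset - 6 else duration - 10)
  }
  cfg <- as.list(environment())
  stopifnot(n_cells >= 1, duration > 40, frame_rate > 0, eeg_fs > 0,
            pis_rate >= 0, pis_participation >= 0, pis_participation <= 1,
            pis_window[1] >= 30, pis_window[2] <= duration)
  if (seizure) {
    span <- field_um * (abs(cos(seizure_angle * pi / 180)) +
                          abs(sin(seizure_angle * pi / 180)))
    stopifnot(seizure_onset + span / seizure_velocity + plateau_dur < duration)
    if (terminal) {
      stopifnot(terminal_onset > seizure_onset + plateau_dur,
                terminal_onset < duration)
    }
  }
  structure(cfg, class = "sim_config")
}

## Double-exponential indicator transient, peak-normalized to 1.
## decay tau = half_decay / ln 2 so the decay half-time matches the indicator.
transient_kernel <- function(t_rel, rise_tau, half_decay) {
  decay_tau <- half_decay / log(2)
  k <- ifelse(t_rel < 0, 0,
              (1 - exp(-t_rel / rise_tau)) * exp(-t_rel / decay_tau))
  t_pk <- rise_tau * log(1 + decay_tau / rise_tau)
  pk <- (1 - exp(-t_pk / rise_tau)) * exp(-t_pk / decay_tau)
  k / pk
}

add_transient <- function(trace, times_axis, onset, amp, rise_tau, half_decay,
                          span = 12 * half_decay + 2) {
  sel <- which(times_axis >= onset & times_axis <= onset + span)
  if (length(sel) == 0L) return(trace)
  trace[sel] <- trace[sel] +
    amp * transient_kernel(times_axis[sel] - onset, rise_tau, half_decay)
  trace
}

## Sustained plateau: fast sigmoidal rise at `onset`, flat top until `offset`,
## then exponential decay.
add_plateau <- function(trace, times_axis, onset, offset, amp,
                        rise_tau = 0.15, decay_tau = 2) {
  up <- which(times_axis >= onset & times_axis < offset)
  trace[up] <- trace[up] + amp * (1 - exp(-(times_axis[up] - onset) / rise_tau))
  dn <- which(times_axis >= offset)
  trace[dn] <- trace[dn] + amp * (1 - exp(-(offset - onset) / rise_tau)) *
    exp(-(times_axis[dn] - offset) / decay_tau)
  trace
}

## Biphasic spike-wave discharge waveform: sharp negative spike (sigma 30 ms)
## followed by a slower positive wave (sigma 120 ms at +250 ms), peak planted
## at t = 0.
swd_waveform <- function(fs, amp, half_width = 0.5) {
  t <- seq(-half_width, half_width, by = 1 / fs)
  -amp * exp(-t^2 / (2 * 0.03^2)) + 0.4 * amp * exp(-(t - 0.25)^2 / (2 * 0.12^2))
}

## steepest-slope time of the clean filtered trace within a window: the time
## an ideal labeler blind to the generator would assign to the event.
label_time <- function(filtered, times_axis, lo, hi) {
  sel <- which(times_axis >= lo & times_axis <= hi)
  if (length(sel) < 2L) return(NA_real_)
  d <- diff(filtered[sel])
  times_axis[sel[which.max(d)]]
}

#' Generate a synthetic paired calcium + EEG recording
#'
#' Builds per-cell clean \eqn{\Delta F/F_0} signals (pre-ictal spike
#' transients with per-cell participation and jitter, an optional sentinel
#' spike, a planar ictal wavefront with sustained plateau, a slow planar
#' terminal spreading wave), adds white + shared noise and slow drift,
#' reconstructs raw soma/neuropil fluorescence by inverting the normalization
#' (known baselines, 70% neuropil coupling), and synthesizes a time-locked EEG
#' (1/f-like background, biphasic spike-wave discharges at the population
#' spike times, rhythmic ictal discharge). Ground truth is returned both as
#' planted parameters and as "label times": the steepest-slope times of the
#' clean filtered traces, i.e. what an ideal labeler marking the point of
#' maximum slope would record.
#'
#' @param cfg a [sim_config()].
#' @return list of class `synthetic_recording`: `calcium`
#'   ([calcium_recording()]), `eeg` ([eeg_recording()]), `truth` (list: see
#'   Details), `config`.
#' @details `truth` carries `pis_times` (population spike times = planted EEG
#'   SWD peaks), `sentinel_time`, `population_spike_times` (both combined),
#'   `eeg_swd_times`, `seizure_seed_time` / `terminal_seed_time` (first
#'   half-max upward crossing of the clean filtered mean neuropil trace),
#'   `cell_events` (data.frame: `cell`, `event_type`, `event_index`,
#'   `planted_time`, `label_time`, `participating`), `wave` (planted seizure /
#'   terminal velocity and angle, per-cell planted recruitment times).
#' @export
generate_recording <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  fr <- cfg$frame_rate
  n_frames <- round(cfg$duration * fr)
  tax <- (seq_len(n_frames) - 1L) / fr
  nc <- cfg$n_cells

  positions <- cbind(x = runif(nc, 0, cfg$field_um),
                     y = runif(nc, 0, cfg$field_um))

  ## population pre-ictal spike times: renewal process with a hard minimum gap
  ## and mean gap 60/rate (so the empirical rate estimates the configured one)
  pis_times <- numeric(0)
  if (cfg$pis_rate > 0 && diff(cfg$pis_window) > cfg$pis_min_gap) {
    mean_gap <- 60 / cfg$pis_rate
    exp_mean <- max(mean_gap - cfg$pis_min_gap, 0.5)
    t_cur <- cfg$pis_window[1L] + rexp(1L, 1 / exp_mean)
    while (t_cur <= cfg$pis_window[2L]) {
      pis_times <- c(pis_times, t_cur)
      t_cur <- t_cur + cfg$pis_min_gap + rexp(1L, 1 / exp_mean)
    }
  }
  n_pis <- length(pis_times)

  sentinel_time <- if (cfg$sentinel) cfg$seizure_onset - runif(1L, 2, 4) else NA_real_

  ## per-cell event structure
  amp <- runif(nc, cfg$pis_amp_range[1L], cfg$pis_amp_range[2L])
  participating <- matrix(runif(nc * n_pis) < cfg$pis_participation, nc, n_pis)
  jitter <- matrix(rnorm(nc * n_pis, 0, cfg$pis_jitter), nc, n_pis)
  event_scale <- matrix(runif(nc * n_pis, 0.85, 1.15), nc, n_pis)

  dir_rad <- cfg$seizure_angle * pi / 180
  proj <- positions[, 1L] * cos(dir_rad) + positions[, 2L] * sin(dir_rad)
  seiz_times_cell <- cfg$seizure_onset + (proj - min(proj)) / cfg$seizure_velocity
  seiz_span <- diff(range(proj)) / cfg$seizure_velocity
  seizure_end <- cfg$seizure_onset + seiz_span + cfg$plateau_dur

  tdir_rad <- cfg$terminal_angle * pi / 180
  tproj <- positions[, 1L] * cos(tdir_rad) + positions[, 2L] * sin(tdir_rad)
  term_times_cell <- cfg$terminal_onset + (tproj - min(tproj)) / cfg$terminal_velocity

  ## clean somatic signals
  clean <- matrix(0, nc, n_frames)
  for (i in seq_len(nc)) {
    tr <- numeric(n_frames)
    for (k in seq_len(n_pis)) {
      if (participating[i, k]) {
        tr <- add_transient(tr, tax, pis_times[k] + jitter[i, k],
                            amp[i] * event_scale[i, k],
                            cfg$rise_tau, cfg$half_decay)
      }
    }
    if (cfg$sentinel) {
      tr <- add_transient(tr, tax, sentinel_time + rnorm(1L, 0, cfg$pis_jitter),
                          amp[i], cfg$rise_tau, cfg$half_decay)
    }
    if (cfg$seizure) {
      tr <- add_plateau(tr, tax, seiz_times_cell[i], seizure_end,
                        cfg$plateau_amp * runif(1L, 0.9, 1.1))
    }
    if (cfg$terminal) {
      tr <- add_transient(tr, tax, term_times_cell[i],
                          cfg$terminal_amp * runif(1L, 0.9, 1.1),
                          rise_tau = 1, half_decay = 6 * log(2))
    }
    clean[i, ] <- tr
  }

  pop_signal <- colMeans(clean)

  ## noisy dff targets
  shared <- rnorm(n_frames, 0, cfg$shared_noise_sd)
  drift_phase <- runif(nc, 0, 2 * pi)
  dff_soma <- clean
  for (i in seq_len(nc)) {
    dff_soma[i, ] <- clean[i, ] + rnorm(n_frames, 0, cfg$noise_sd) + shared +
      cfg$drift_amp * sin(2 * pi * tax / 120 + drift_phase[i])
  }
  dff_npil <- matrix(0, nc, n_frames)
  for (i in seq_len(nc)) {
    dff_npil[i, ] <- cfg$neuropil_coupling * pop_signal +
      rnorm(n_frames, 0, cfg$noise_sd / 2) + shared
  }

  ## invert the normalization into raw fluorescence (a.u.)
  f0_soma <- runif(nc, 300, 600)
  f0_npil <- runif(nc, 150, 300)
  b0 <- 50
  neuropil_raw <- b0 + f0_npil * (1 + dff_npil)
  b_actual <- min(neuropil_raw)
  corrected <- f0_soma * (1 + dff_soma)
  soma_raw <- b_actual + corrected + 0.7 * (neuropil_raw - b_actual)

  calcium <- calcium_recording(soma_raw, neuropil_raw, positions, fr)

  ## EEG: AR(1) 1/f-like background + SWDs at population spike times (and the
  ## sentinel) + rhythmic 6-Hz ictal discharge
  n_eeg <- round(cfg$duration * cfg$eeg_fs)
  eeg_x <- as.numeric(stats::filter(rnorm(n_eeg), 0.99, method = "recursive"))
  eeg_x <- eeg_x / stats::sd(eeg_x) * cfg$eeg_noise_sd
  swd_times <- c(pis_times, if (cfg$sentinel) sentinel_time)
  w <- swd_waveform(cfg$eeg_fs, cfg$swd_amp * cfg$eeg_noise_sd)
  hw <- (length(w) - 1L) %/% 2L
  for (tt in swd_times) {
    c0 <- round(tt * cfg$eeg_fs) + 1L
    idx <- (c0 - hw):(c0 + hw)
    ok <- idx >= 1L & idx <= n_eeg
    eeg_x[idx[ok]] <- eeg_x[idx[ok]] + w[ok]
  }
  if (cfg$seizure) {
    tz <- seq(0, seizure_end - cfg$seizure_onset, by = 1 / cfg$eeg_fs)
    i0 <- round(cfg$seizure_onset * cfg$eeg_fs) + 1L
    idx <- i0 + seq_along(tz) - 1L
    ok <- idx <= n_eeg
    eeg_x[idx[ok]] <- eeg_x[idx[ok]] +
      0.8 * cfg$swd_amp * cfg$eeg_noise_sd * sin(2 * pi * 6 * tz[ok])
  }
  eeg <- eeg_recording(eeg_x, cfg$eeg_fs)

  ## ground-truth label times from clean signals
  mean_npil_clean <- cfg$neuropil_coupling * pop_signal
  mean_npil_f <- zero_phase_lowpass(mean_npil_clean, fr)
  half_max <- 0.5 * max(mean_npil_f)
  first_crossing <- function(lo, hi) {
    sel <- which(tax >= lo & tax <= hi)
    above <- mean_npil_f[sel] >= half_max
    if (!any(above)) return(NA_real_)
    tax[sel[which(above)[1L]]]
  }
  seizure_seed <- if (cfg$seizure) {
    first_crossing(cfg$seizure_onset - 2, seizure_end)
  } else NA_real_
  terminal_seed <- if (cfg$terminal) {
    first_crossing(cfg$terminal_onset - 2, cfg$duration)
  } else NA_real_

  cell_events <- list()
  for (i in seq_len(nc)) {
    cf <- zero_phase_lowpass(clean[i, ], fr)
    if (n_pis > 0L) {
      lt <- vapply(seq_len(n_pis), function(k) {
        if (!participating[i, k]) return(NA_real_)
        label_time(cf, tax, pis_times[k] + jitter[i, k] - 0.5,
                   pis_times[k] + jitter[i, k] + 1.5)
      }, numeric(1L))
      cell_events[[length(cell_events) + 1L]] <- data.frame(
        cell = i, event_type = "pis", event_index = seq_len(n_pis),
        planted_time = pis_times + jitter[i, ],
        label_time = lt, participating = participating[i, ])
    }
    if (cfg$sentinel) {
      cell_events[[length(cell_events) + 1L]] <- data.frame(
        cell = i, event_type = "sentinel", event_index = 1L,
        planted_time = sentinel_time,
        label_time = label_time(cf, tax, sentinel_time - 0.5,
                                sentinel_time + 1.5),
        participating = TRUE)
    }
    if (cfg$seizure) {
      cell_events[[length(cell_events) + 1L]] <- data.frame(
        cell = i, event_type = "seizure", event_index = 1L,
        planted_time = seiz_times_cell[i],
        label_time = label_time(cf, tax, seiz_times_cell[i] - 1,
                                seiz_times_cell[i] + 2),
        participating = TRUE)
    }
    if (cfg$terminal) {
      cell_events[[length(cell_events) + 1L]] <- data.frame(
        cell = i, event_type = "terminal", event_index = 1L,
        planted_time = term_times_cell[i],
        label_time = label_time(cf, tax, term_times_cell[i] - 2,
                                term_times_cell[i] + 4),
        participating = TRUE)
    }
  }
  cell_events <- if (length(cell_events)) do.call(rbind, cell_events) else
    data.frame(cell = integer(0), event_type = character(0),
               event_index = integer(0), planted_time = numeric(0),
               label_time = numeric(0), participating = logical(0))

  truth <- list(
    pis_times = pis_times,
    sentinel_time = sentinel_time,
    population_spike_times = sort(c(pis_times,
                                    if (cfg$sentinel) sentinel_time)),
    eeg_swd_times = sort(swd_times),
    seizure_seed_time = seizure_seed,
    terminal_seed_time = terminal_seed,
    cell_events = cell_events,
    wave = list(
      seizure = if (cfg$seizure) list(velocity = cfg$seizure_velocity,
                                      angle = cfg$seizure_angle,
                                      cell_times = seiz_times_cell) else NULL,
      terminal = if (cfg$terminal) list(velocity = cfg$terminal_velocity,
                                        angle = cfg$terminal_angle,
                                        cell_times = term_times_cell) else NULL)
  )

  structure(list(calcium = calcium, eeg = eeg, truth = truth, config = cfg),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %d cells, %.0f s, %d pre-ictal spikes, seizure %s, terminal %s\n",
              x$config$n_cells, x$config$duration, length(x$truth$pis_times),
              if (x$config$seizure) "yes" else "no",
              if (x$config$terminal) "yes" else "no"))
  invisible(x)
}
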