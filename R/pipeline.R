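#' Pipeline configuration
#'
#' All tunables of the detection pipeline, defaulting to the method's
#' published constants: 1-Hz zero-phase low-pass; 15% / 20% slope-integral
#' rank cuts for population / per-cell stages; 0.33-s model-spike sigma;
#' 0.2-s calcium--EEG reconciliation; EEG rules (4.5 robust SD threshold,
#' 3--15 / 20--55 Hz ratio >= 20, 0.7-s ISI, 5-SD / 1-s kernel recovery);
#' per-cell rules (1.5-s / 4-sigma pre-ictal spikes; Gaussian sigma 1 s / 5 s,
#' tolerance 3 s / 5 s, windows 10 s / 5 s and 20% increase for seizure /
#' terminal waves); 1-s evaluation matching. Any override is recorded in the
#' run log together with a hash of the full configuration.
#'
#' @param ... named overrides of the defaults listed above.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    lowpass_hz = 1,
    filter_orders = c(3, 5),
    neuropil_coeff = 0.7,
    baseline_window = 30,
    pop_top_frac = 0.15,
    model_sigma = 0.33,
    eeg_k_sd = 4.5,
    eeg_min_separation = 0.7,
    ratio_min = 20,
    isi_min = 0.7,
    kernel_half_width = 0.5,
    recover_k_sd = 5,
    recover_min_separation = 1,
    recover_dedup_tol = 0.5,
    reconcile_tol = 0.2,
    cell_top_frac = 0.20,
    pis_cell_tol = 1.5,
    pis_peak_z = 4,
    pis_stat_margin = 10,
    seizure_sigma = 1, seizure_tol = 3, seizure_window = 10,
    terminal_sigma = 5, terminal_tol = 5, terminal_window = 5,
    increase_min = 1.2,
    match_tol = 1,
    f1_method = "geometric",
    l1_lambda = "auto",
    n_shuffles = 1000,
    rng_seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("pipeline_config: unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  attr(cfg, "overrides") <- names(overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> hash", rlang::hash(unclass(x)), "\n")
  ov <- attr(x, "overrides")
  if (length(ov)) cat("  overridden:", paste(ov, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full detection pipeline
#'
#' Executes the stages in order: preprocessing (background subtraction,
#' neuropil correction, \eqn{\Delta F/F_0}), wavefront seed detection on the
#' filtered population-mean neuropil trace, EEG spike-wave discharge detection
#' (threshold + spectral-ratio exclusion), population pre-ictal spike
#' detection on the pre-ictal portion of the mean neuropil trace, calcium--EEG
#' reconciliation, matched-kernel recovery of missed spikes, and per-cell
#' recruitment detection for all three event types. Pre-ictal spike detection
#' is restricted to times before the detected seizure onset (the ictal
#' rhythmic discharge would otherwise be re-detected as spikes); the
#' kernel-recovery stage is skipped with a log entry when no concordant spike
#' exists.
#'
#' @param calcium a [calcium_recording()].
#' @param eeg an [eeg_recording()] (required: pre-ictal spike times are
#'   EEG-reconciled by construction).
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; when given, event/recruitment CSVs and a
#'   JSON run log are written there.
#' @return list of class `ictal_detection`: `seeds` ([event_seeds()]),
#'   `recruitment` (data.frame), `norm` (`normalized_traces`), `eeg_spikes`
#'   (`eeg_spike_set`), `log` (character).
#' @export
run_pipeline <- function(calcium, eeg, cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(calcium, "calcium_recording"))
  if (!inherits(eeg, "eeg_recording")) {
    stop("run_pipeline: an EEG recording is required (stage eeg_events): ",
         "pre-ictal spike times are reconciled against EEG by construction")
  }
  log <- c(sprintf("config_hash %s", rlang::hash(unclass(cfg))),
           sprintf("overrides %s",
                   paste(attr(cfg, "overrides") %||% "none", collapse = ",")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("run_pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  norm <- stage("signal_core", preprocess_traces(
    calcium, neuropil_coeff = cfg$neuropil_coeff,
    baseline_window = cfg$baseline_window))

  fr <- calcium$frame_rate
  t0 <- calcium$t0_offset
  mean_f <- stage("signal_core", zero_phase_lowpass(
    norm$mean_neuropil, fr, cutoff = cfg$lowpass_hz,
    order_range = cfg$filter_orders))
  log <- c(log, sprintf("filter_order %d", attr(mean_f, "order")))

  waves <- stage("population_events", detect_wavefronts(mean_f, fr, t0))
  log <- c(log, sprintf("seizure_seed %s terminal_seed %s",
                        format(waves$seizure_time), format(waves$terminal_time)))

  ## pre-ictal portion: everything before the seizure seed (whole trace
  ## when no seizure was found)
  pre_end <- if (!is.na(waves$seizure_time)) waves$seizure_time else Inf
  tax <- t0 + (seq_along(mean_f) - 1L) / fr
  pre_idx <- which(tax < pre_end)

  eeg_spikes <- stage("eeg_events", {
    sp <- detect_eeg_spikes_threshold(eeg, cfg$eeg_k_sd, cfg$eeg_min_separation)
    sp_pre <- new_spike_set(sp$times[sp$times < pre_end],
                            sp$source[sp$times < pre_end])
    spectral_ratio_filter(eeg, sp_pre, cfg$ratio_min, cfg$isi_min)
  })
  log <- c(log, sprintf("eeg_spikes_threshold %d", length(eeg_spikes$times)))

  ca_cand <- stage("population_events", detect_population_spikes(
    mean_f[pre_idx], fr, t0 = tax[pre_idx][1L], top_frac = cfg$pop_top_frac,
    sigma = cfg$model_sigma))
  log <- c(log, sprintf("calcium_candidates %d", length(ca_cand)))

  rec <- stage("population_events",
               reconcile_with_eeg(ca_cand, eeg_spikes, cfg$reconcile_tol))
  pis <- rec$pis_times
  prov <- rep("concordant", length(pis))

  if (length(pis) > 0L) {
    recovered <- stage("eeg_events", {
      kern <- build_swd_kernel(eeg, pis, cfg$kernel_half_width)
      all_sp <- recover_missed_spikes(
        eeg, kern, new_spike_set(pis, rep("threshold", length(pis))),
        cfg$recover_k_sd, cfg$recover_min_separation, cfg$recover_dedup_tol)
      all_sp$times[all_sp$source == "kernel_recovered" & all_sp$times < pre_end]
    })
    log <- c(log, sprintf("kernel_recovered %d", length(recovered)))
    pis <- c(pis, recovered)
    prov <- c(prov, rep("kernel_recovered", length(recovered)))
  } else {
    log <- c(log, "kernel_recovered skipped (no concordant spikes)")
  }

  seeds <- event_seeds(pis, waves$seizure_time, waves$terminal_time, prov)
  recruitment <- stage("cell_recruitment", detect_recruitment(norm, seeds, cfg))

  res <- structure(list(seeds = seeds, recruitment = recruitment, norm = norm,
                        eeg_spikes = eeg_spikes, log = log, config = cfg),
                   class = "ictal_detection")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events_csv(seeds, file.path(out_dir, "events.csv"))
    write_recruitment_csv(recruitment, file.path(out_dir, "recruitment.csv"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  res
}

#' @export
print.ictal_detection <- function(x, ...) {
  print(x$seeds)
  cat(sprintf("  %d recruitment rows (%d recruited) across %d cells\n",
              nrow(x$recruitment), sum(x$recruitment$recruited),
              length(unique(x$recruitment$cell))))
  invisible(x)
}
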