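#' Read a calcium recording from a fixture directory
#'
#' Expects the CSV layout written by [export_fixture()] (the plain-text
#' mirror of Suite2p's `F.npy` / `Fneu.npy` / `iscell.npy` / `stat` arrays):
#' `F.csv` and `Fneu.csv` (cells x frames, no header), `positions.csv`
#' (columns `x`, `y` in micrometers), `iscell.csv` (one 0/1 column), and
#' `meta.json` (`frame_rate`, `t0_offset`). Rows with `iscell == 0` are
#' dropped.
#'
#' @param dir fixture directory.
#' @return a [calcium_recording()].
#' @export
read_calcium_dir <- function(dir) {
  f <- as.matrix(data.table::fread(file.path(dir, "F.csv"), header = FALSE))
  fneu <- as.matrix(data.table::fread(file.path(dir, "Fneu.csv"), header = FALSE))
  pos <- as.data.frame(data.table::fread(file.path(dir, "positions.csv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  iscell_path <- file.path(dir, "iscell.csv")
  keep <- if (file.exists(iscell_path)) {
    as.logical(data.table::fread(iscell_path, header = FALSE)[[1L]])
  } else rep(TRUE, nrow(f))
  calcium_recording(f[keep, , drop = FALSE], fneu[keep, , drop = FALSE],
                    pos[keep, c("x", "y")], meta$frame_rate,
                    t0_offset = meta$t0_offset %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an EEG recording from a two-column CSV
#'
#' Columns `time_s` and `value` (headers required); the sampling rate is
#' inferred from the median time step.
#'
#' @param path CSV path.
#' @param bandpass acquisition bandpass metadata, Hz.
#' @return an [eeg_recording()].
#' @export
read_eeg_csv <- function(path, bandpass = c(0.5, 300)) {
  d <- data.table::fread(path)
  stopifnot(all(c("time_s", "value") %in% names(d)))
  fs <- 1 / median(diff(d$time_s))
  eeg_recording(d$value, fs = round(fs, 6), bandpass = bandpass,
                t0 = d$time_s[1L])
}

#' Write an EEG recording to a two-column CSV
#' @param eeg an [eeg_recording()].
#' @param path output path.
#' @export
write_eeg_csv <- function(eeg, path) {
  data.table::fwrite(data.frame(time_s = eeg_times(eeg), value = eeg$samples),
                     path)
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' Minimal reader for EDF (European Data Format, 16-bit): parses the header,
#' selects one signal, and converts digital samples to physical units via the
#' per-signal calibration. Sufficient for single-channel rodent EEG exports.
#'
#' @param path EDF file.
#' @param channel signal index (default 1) or label.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  fld <- function(width) {
    vapply(seq_len(ns), function(i) trimws(readChar(con, width, useBytes = TRUE)),
           character(1L))
  }
  labels <- fld(16); fld(80); fld(8)                     # label, transducer, unit
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                                                # prefiltering
  n_samp <- as.integer(fld(8)); fld(32)                  # samples/record, reserved
  ch <- if (is.character(channel)) match(channel, labels) else as.integer(channel)
  if (is.na(ch) || ch < 1L || ch > ns) stop("read_edf: channel not found")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = n_samp[s], size = 2L, endian = "little")
      if (s == ch) out[[r]] <- v
    }
  }
  x <- phys_min[ch] + (unlist(out) - dig_min[ch]) * gain[ch]
  eeg_recording(x, fs = n_samp[ch] / rec_dur)
}

#' Write a single-channel EDF file
#'
#' Counterpart of [read_edf()]. Samples are scaled into the 16-bit digital
#' range, so the round trip is exact only up to EDF's quantization
#' (`(max - min) / 65535` per step).
#'
#' @param eeg an [eeg_recording()].
#' @param path output path.
#' @param label signal label (default "EEG").
#' @export
write_edf <- function(eeg, path, label = "EEG") {
  fs <- eeg$fs
  rec_dur <- 1
  n_samp <- round(fs * rec_dur)
  n_rec <- ceiling(length(eeg$samples) / n_samp)
  x <- c(eeg$samples, rep(0, n_rec * n_samp - length(eeg$samples)))
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768; dmax <- 32767
  dig <- as.integer(round(dmin + (x - pmin_) / (pmax_ - pmin_) * (dmax - dmin)))
  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("synthetic", 80), pad("synthetic", 80),
                   pad("01.01.26", 8), pad("00.00.00", 8), pad(256 + 256, 8),
                   pad("", 44), pad(n_rec, 8), pad(rec_dur, 8), pad(1, 4)),
            con, eos = NULL, useBytes = TRUE)
  writeChar(paste0(pad(label, 16), pad("", 80), pad("au", 8),
                   pad(format(pmin_, digits = 6), 8),
                   pad(format(pmax_, digits = 6), 8),
                   pad(dmin, 8), pad(dmax, 8), pad("", 80), pad(n_samp, 8),
                   pad("", 32)),
            con, eos = NULL, useBytes = TRUE)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Export a synthetic recording as a plain-text fixture
#'
#' Writes the Suite2p-convention CSV arrays, the EEG (CSV, optionally EDF),
#' the ground-truth tables and the generator configuration into a directory,
#' so the recording round-trips through the package readers.
#'
#' @param sim a `synthetic_recording` from [generate_recording()].
#' @param dir output directory (created if needed).
#' @param edf also write `eeg.edf` (default FALSE; EDF quantizes to 16 bits).
#' @return `dir`, invisibly.
#' @export
export_fixture <- function(sim, dir, edf = FALSE) {
  stopifnot(inherits(sim, "synthetic_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- sim$calcium
  data.table::fwrite(as.data.frame(rec$soma_raw), file.path(dir, "F.csv"),
                     col.names = FALSE)
  data.table::fwrite(as.data.frame(rec$neuropil_raw), file.path(dir, "Fneu.csv"),
                     col.names = FALSE)
  data.table::fwrite(as.data.frame(rec$positions), file.path(dir, "positions.csv"))
  data.table::fwrite(data.frame(iscell = rep(1L, nrow(rec$soma_raw))),
                     file.path(dir, "iscell.csv"), col.names = FALSE)
  jsonlite::write_json(list(frame_rate = rec$frame_rate,
                            t0_offset = rec$t0_offset),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_eeg_csv(sim$eeg, file.path(dir, "eeg.csv"))
  if (edf) write_edf(sim$eeg, file.path(dir, "eeg.edf"))
  tr <- sim$truth
  data.table::fwrite(tr$cell_events, file.path(dir, "truth_cell_events.csv"))
  data.table::fwrite(
    data.frame(event_type = c(rep("pis", length(tr$pis_times)),
                              if (!is.na(tr$sentinel_time)) "sentinel",
                              if (!is.na(tr$seizure_seed_time)) "seizure",
                              if (!is.na(tr$terminal_seed_time)) "terminal"),
               time_s = c(tr$pis_times,
                          if (!is.na(tr$sentinel_time)) tr$sentinel_time,
                          if (!is.na(tr$seizure_seed_time)) tr$seizure_seed_time,
                          if (!is.na(tr$terminal_seed_time)) tr$terminal_seed_time)),
    file.path(dir, "truth_population_events.csv"))
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write population event seeds to CSV
#' @param seeds an [event_seeds()].
#' @param path output CSV (columns `event_type`, `time_s`, `provenance`).
#' @export
write_events_csv <- function(seeds, path) {
  df <- data.frame(
    event_type = c(rep("pis", length(seeds$pis_times)),
                   if (!is.na(seeds$seizure_time)) "seizure",
                   if (!is.na(seeds$terminal_time)) "terminal"),
    time_s = c(seeds$pis_times,
               if (!is.na(seeds$seizure_time)) seeds$seizure_time,
               if (!is.na(seeds$terminal_time)) seeds$terminal_time),
    provenance = c(seeds$provenance,
                   if (!is.na(seeds$seizure_time)) "half_max",
                   if (!is.na(seeds$terminal_time)) "half_max"))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Write a per-cell recruitment table to CSV
#' @param recruitment data.frame from [detect_recruitment()].
#' @param path output CSV.
#' @export
write_recruitment_csv <- function(recruitment, path) {
  out <- recruitment[, c("cell", "event_type", "seed_time", "recruited",
                         "recruitment_time", "feature")]
  names(out) <- c("cell", "event_type", "seed_time_s", "recruited", "time_s",
                  "feature")
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a manual event-label CSV
#'
#' Expected columns: `event_type`, `time_s`, and `cell` (integer index or
#' `"population"`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_labels_csv <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("event_type", "time_s") %in% names(d)))
  if (!"cell" %in% names(d)) d$cell <- "population"
  d
}
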