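#' Per-cell pre-ictal spike recruitment
#'
#' Seed-guided detection of individual-cell recruitment to pre-ictal spikes.
#' The cell's positive-slope segments are ranked by slope-integral and the top
#' `top_frac` retained (at least as many segments as there are seeds are kept:
#' the fraction cut assumes a noise-dominated segment population and would
#' otherwise starve the candidate pool on near-noise-free traces). Seeds and
#' retained segments are then paired one-to-one, nearest first (a segment
#' serves at most one seed). A cell is recruited to a seed when its candidate
#' segment's steepest-slope time falls within `tol` of the seed time and the
#' segment's peak exceeds the cell's center by `peak_z` spreads. Center and
#' spread are the median and the scaled median absolute deviation of the
#' pre-ictal portion of the filtered trace (up to `stat_end` seconds; the
#' whole trace by default): on noise-dominated traces this equals the mean /
#' 4-SD rule, while staying well-defined when sparse large events themselves
#' carry most of the trace variance (ictal plateaus or near-noise-free
#' recordings would otherwise inflate the spread with the very events being
#' detected).
#'
#' @param cell_dff_filtered the cell's filtered \eqn{\Delta F/F_0} trace.
#' @param frame_rate Hz.
#' @param pis_seeds sorted seed times (seconds).
#' @param t0 time of the first sample, seconds.
#' @param top_frac fraction of segments retained by rank (default 0.20).
#' @param tol maximum |candidate - seed| for recruitment, seconds (default 1.5).
#' @param peak_z peak threshold in SDs above the cell mean (default 4).
#' @param stat_end end of the window used for the mean/SD statistics, seconds
#'   (e.g. seizure seed minus 10 s); `NULL` uses the full trace.
#' @return data.frame, one row per seed: `event_type` (`"pis"`),
#'   `seed_time`, `recruited`, `recruitment_time` (`NA` when not recruited),
#'   `feature` (slope-integral), `peak_z` (criterion value).
#' @export
detect_cell_pis <- function(cell_dff_filtered, frame_rate, pis_seeds, t0 = 0,
                            top_frac = 0.20, tol = 1.5, peak_z = 4,
                            stat_end = NULL) {
  x <- as.numeric(cell_dff_filtered)
  out <- data.frame(event_type = rep("pis", length(pis_seeds)),
                    seed_time = pis_seeds,
                    recruited = FALSE,
                    recruitment_time = NA_real_,
                    feature = NA_real_,
                    peak_z = NA_real_)
  if (length(pis_seeds) == 0L) return(out)
  segs <- positive_slope_segments(x, frame_rate, t0)
  if (nrow(segs) == 0L) return(out)

  times <- t0 + (seq_along(x) - 1L) / frame_rate
  stat_idx <- if (is.null(stat_end)) seq_along(x) else which(times <= stat_end)
  if (length(stat_idx) < 2L) stat_idx <- seq_along(x)
  mu <- stats::median(x[stat_idx])
  sdev <- stats::mad(x[stat_idx])

  n_keep <- min(nrow(segs), max(ceiling(top_frac * nrow(segs)),
                                length(pis_seeds)))
  segs <- segs[order(-segs$slope_integral)[seq_len(n_keep)], , drop = FALSE]

  ## one-to-one nearest pairing of seeds and retained segments
  pairs <- expand.grid(si = seq_along(pis_seeds), gi = seq_len(nrow(segs)))
  pairs$d <- abs(pis_seeds[pairs$si] - segs$index_time[pairs$gi])
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_s <- rep(FALSE, length(pis_seeds))
  used_g <- rep(FALSE, nrow(segs))
  for (r in seq_len(nrow(pairs))) {
    si <- pairs$si[r]; gi <- pairs$gi[r]
    if (used_s[si] || used_g[gi]) next
    used_s[si] <- TRUE; used_g[gi] <- TRUE
    z <- if (sdev > 0) (segs$peak_value[gi] - mu) / sdev else Inf
    out$recruitment_time[si] <- segs$index_time[gi]
    out$feature[si] <- segs$slope_integral[gi]
    out$peak_z[si] <- z
    out$recruited[si] <- pairs$d[r] <= tol && z > peak_z
  }
  out$recruitment_time[!out$recruited] <- NA_real_
  out
}

#' Per-cell wavefront recruitment
#'
#' Seed-guided detection of a cell's recruitment to the seizure wavefront or
#' the terminal spreading wave. Every positive-slope segment's slope-integral
#' is multiplied by a Gaussian weight of its steepest-slope time's distance to
#' the seed (`sigma` 1 s for the seizure -- narrow, to reject the sentinel
#' spike that often precedes ictal invasion by a few seconds -- and 5 s for the
#' slower terminal wave). The maximally weighted segment's steepest-slope time
#' is the recruitment time; the cell is recruited when the trace mean over
#' `window` seconds after that time is at least `increase_min` times the mean
#' over `window` seconds before it (windows truncated at the record edges) and
#' the time is within `tol` of the seed.
#'
#' @param cell_dff_filtered the cell's filtered \eqn{\Delta F/F_0} trace.
#' @param frame_rate Hz.
#' @param seed seed time, seconds.
#' @param kind `"seizure"` or `"terminal"`.
#' @param t0 time of the first sample, seconds.
#' @param sigma Gaussian weighting SD, seconds; default 1 (seizure) / 5
#'   (terminal).
#' @param tol recruitment-time tolerance, seconds; default 3 (seizure) / 5
#'   (terminal).
#' @param window before/after averaging window, seconds; default 10 (seizure,
#'   leveraging the sustained ictal plateau) / 5 (terminal, where calcium
#'   levels between seizure and terminal wave vary more).
#' @param increase_min required post/pre mean ratio (default 1.2).
#' @return one-row data.frame: `event_type`, `seed_time`, `recruited`,
#'   `recruitment_time`, `feature` (weighted slope-integral), `mean_ratio`.
#' @export
detect_cell_wavefront <- function(cell_dff_filtered, frame_rate, seed,
                                  kind = c("seizure", "terminal"), t0 = 0,
                                  sigma = NULL, tol = NULL, window = NULL,
                                  increase_min = 1.2) {
  kind <- match.arg(kind)
  defaults <- list(seizure = c(sigma = 1, tol = 3, window = 10),
                   terminal = c(sigma = 5, tol = 5, window = 5))[[kind]]
  if (is.null(sigma)) sigma <- defaults[["sigma"]]
  if (is.null(tol)) tol <- defaults[["tol"]]
  if (is.null(window)) window <- defaults[["window"]]

  x <- as.numeric(cell_dff_filtered)
  out <- data.frame(event_type = kind, seed_time = seed, recruited = FALSE,
                    recruitment_time = NA_real_, feature = NA_real_,
                    mean_ratio = NA_real_)
  segs <- positive_slope_segments(x, frame_rate, t0)
  if (nrow(segs) == 0L || is.na(seed)) return(out)

  w <- exp(-(segs$index_time - seed)^2 / (2 * sigma^2))
  weighted <- segs$slope_integral * w
  best <- which.max(weighted)
  t_rec <- segs$index_time[best]

  n <- length(x)
  i_rec <- round((t_rec - t0) * frame_rate) + 1L
  wlen <- round(window * frame_rate)
  pre_idx <- max(1L, i_rec - wlen):max(1L, i_rec - 1L)
  post_idx <- min(n, i_rec + 1L):min(n, i_rec + wlen)
  mean_pre <- mean(x[pre_idx])
  mean_post <- mean(x[post_idx])
  ratio <- mean_post / mean_pre

  out$recruitment_time <- t_rec
  out$feature <- weighted[best]
  out$mean_ratio <- ratio
  out$recruited <- (mean_post >= increase_min * mean_pre) &&
    abs(t_rec - seed) <= tol
  if (!out$recruited) out$recruitment_time <- NA_real_
  out
}

#' Per-cell recruitment across all events and cells
#'
#' Runs [detect_cell_pis()] and [detect_cell_wavefront()] for every valid cell
#' against the population seeds and binds the results into one table.
#'
#' @param norm a `normalized_traces` object from [preprocess_traces()].
#' @param seeds an [event_seeds()] object.
#' @param cfg a [pipeline_config()] (tunables; defaults used when `NULL`).
#' @return data.frame with columns `cell`, `event_type`, `seed_time`,
#'   `recruited`, `recruitment_time`, `feature`, plus criterion columns.
#' @export
detect_recruitment <- function(norm, seeds, cfg = NULL) {
  if (is.null(cfg)) cfg <- pipeline_config()
  fr <- norm$frame_rate
  t0 <- norm$t0_offset
  stat_end <- if (!is.na(seeds$seizure_time)) {
    seeds$seizure_time - cfg$pis_stat_margin
  } else NULL

  res <- lapply(which(norm$valid), function(ci) {
    xf <- zero_phase_lowpass(norm$dff_soma[ci, ], fr, cutoff = cfg$lowpass_hz)
    rows <- list()
    if (length(seeds$pis_times) > 0L) {
      r <- detect_cell_pis(xf, fr, seeds$pis_times, t0 = t0,
                           top_frac = cfg$cell_top_frac, tol = cfg$pis_cell_tol,
                           peak_z = cfg$pis_peak_z, stat_end = stat_end)
      r$mean_ratio <- NA_real_
      rows <- c(rows, list(r))
    }
    if (!is.na(seeds$seizure_time)) {
      r <- detect_cell_wavefront(xf, fr, seeds$seizure_time, "seizure", t0 = t0)
      r$peak_z <- NA_real_
      rows <- c(rows, list(r[, c("event_type", "seed_time", "recruited",
                                 "recruitment_time", "feature", "peak_z",
                                 "mean_ratio")]))
    }
    if (!is.na(seeds$terminal_time)) {
      r <- detect_cell_wavefront(xf, fr, seeds$terminal_time, "terminal", t0 = t0)
      r$peak_z <- NA_real_
      rows <- c(rows, list(r[, c("event_type", "seed_time", "recruited",
                                 "recruitment_time", "feature", "peak_z",
                                 "mean_ratio")]))
    }
    if (length(rows) == 0L) return(NULL)
    df <- do.call(rbind, lapply(rows, function(d) {
      d[, c("event_type", "seed_time", "recruited", "recruitment_time",
            "feature", "peak_z", "mean_ratio")]
    }))
    df$cell <- ci
    df
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(cell = integer(0), event_type = character(0),
                      seed_time = numeric(0), recruited = logical(0),
                      recruitment_time = numeric(0), feature = numeric(0),
                      peak_z = numeric(0), mean_ratio = numeric(0)))
  }
  rownames(res) <- NULL
  res[, c("cell", "event_type", "seed_time", "recruited", "recruitment_time",
          "feature", "peak_z", "mean_ratio")]
}
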