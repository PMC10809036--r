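#' Match detected events to manual labels within a tolerance
#'
#' Iterates through manual events chronologically; each is matched to the
#' nearest unused detected event within `tol` seconds (ties broken toward the
#' earlier detected event). Unmatched manual events are false negatives,
#' unmatched detected events false positives.
#'
#' @param manual sorted manual event times, seconds.
#' @param detected sorted detected event times, seconds.
#' @param tol matching tolerance, seconds (default 1).
#' @return list of class `match_counts`: `tp`, `fp`, `fn`.
#' @export
match_events <- function(manual, detected, tol = 1) {
  manual <- sort(manual)
  detected <- sort(detected)
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (m in manual) {
    d <- abs(detected - m)
    d[used] <- Inf
    if (length(d) > 0L && min(d) <= tol) {
      used[which.min(d)] <- TRUE   # which.min takes the earlier on ties
      tp <- tp + 1L
    }
  }
  structure(list(tp = tp, fp = sum(!used), fn = length(manual) - tp),
            class = "match_counts")
}

#' Detection accuracy
#'
#' `TP / (TP + FP + FN)`. True negatives are ill-defined for sparse event
#' detection, so this "accuracy" has no TN term and chance level is far below
#' 0.5 (see [poisson_baseline()]).
#'
#' @param c a `match_counts` from [match_events()] (or a list with `tp`, `fp`,
#'   `fn`).
#' @return fraction in \[0, 1\].
#' @export
accuracy <- function(c) {
  tot <- c$tp + c$fp + c$fn
  if (tot == 0) stop("accuracy undefined: tp = fp = fn = 0")
  c$tp / tot
}

#' F1 score
#'
#' Geometric mean of precision (positive predictive value) and recall
#' (sensitivity): `sqrt(TP/(TP+FP) * TP/(TP+FN))`. `method = "product"` gives
#' the plain product of the two instead.
#'
#' @param c a `match_counts`.
#' @param method `"geometric"` (default) or `"product"`.
#' @return fraction in \[0, 1\]; 0 when `tp = 0` with any `fp`/`fn`.
#' @export
f1_score <- function(c, method = c("geometric", "product")) {
  method <- match.arg(method)
  if (c$tp + c$fp + c$fn == 0) stop("f1 undefined: tp = fp = fn = 0")
  if (c$tp == 0) return(0)
  prec <- c$tp / (c$tp + c$fp)
  rec <- c$tp / (c$tp + c$fn)
  if (method == "geometric") sqrt(prec * rec) else prec * rec
}

#' Poisson chance baseline for event detection
#'
#' Simulates random-chance detection: a homogeneous Poisson process at the
#' manual events' empirical rate generates detected times on `[0, duration]`,
#' which are matched against the manual labels and scored; the mean F1 over
#' `n_reps` repetitions is the chance baseline.
#'
#' @param manual manual event times, seconds.
#' @param duration record (pre-ictal period) duration, seconds.
#' @param n_reps repetitions (default 50).
#' @param tol matching tolerance, seconds (default 1).
#' @param rng_seed optional integer seed.
#' @return mean F1 over repetitions (0 when `manual` is empty).
#' @export
poisson_baseline <- function(manual, duration, n_reps = 50, tol = 1,
                             rng_seed = NULL) {
  stopifnot(duration > 0)
  if (length(manual) == 0L) return(0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  lambda <- length(manual) / duration
  f1s <- vapply(seq_len(n_reps), function(i) {
    n <- rpois(1L, lambda * duration)
    det <- sort(runif(n, 0, duration))
    f1_score(match_events(manual, det, tol))
  }, numeric(1L))
  mean(f1s)
}

## Topographic prominence of local maxima: peak height minus the higher of the
## two lowest points separating it from higher terrain on each side.
find_peaks <- function(x, prominence_min = 0) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(0), height = numeric(0),
                                prominence = numeric(0)))
  is_pk <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(is_pk) == 0L) return(data.frame(index = integer(0),
                                             height = numeric(0),
                                             prominence = numeric(0)))
  ## scans stop at the first higher sample, so the amortized cost stays low
  prom <- vapply(is_pk, function(i) {
    h <- x[i]
    base_l <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < base_l) base_l <- x[j]
      j <- j - 1L
    }
    base_r <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < base_r) base_r <- x[j]
      j <- j + 1L
    }
    h - max(base_l, base_r)
  }, numeric(1L))
  keep <- prom > prominence_min
  data.frame(index = is_pk[keep], height = x[is_pk[keep]],
             prominence = prom[keep])
}

#' Pre-ictal signal-to-noise ratio of a cell
#'
#' SNR = mean \eqn{\Delta F/F_0} height of all peaks with topographic
#' prominence above `prominence_min` within the pre-ictal window, divided by
#' the baseline variability quantified as the 40th minus 10th percentile of
#' the windowed series (a spread that excludes both outliers and the peaks
#' themselves).
#'
#' @param cell_dff the cell's \eqn{\Delta F/F_0} trace (unfiltered).
#' @param frame_rate Hz.
#' @param preictal_window length-2 numeric, window in seconds.
#' @param t0 time of the first sample, seconds.
#' @param prominence_min minimum peak prominence, \eqn{\Delta F/F_0}
#'   (default 1).
#' @return list of class `snr_record`: `snr` (`NA` when undefined), `n_peaks`,
#'   `noise_spread`.
#' @export
compute_snr <- function(cell_dff, frame_rate, preictal_window, t0 = 0,
                        prominence_min = 1) {
  times <- t0 + (seq_along(cell_dff) - 1L) / frame_rate
  sel <- times >= preictal_window[1L] & times <= preictal_window[2L]
  if (!any(sel)) stop("empty pre-ictal window")
  x <- as.numeric(cell_dff[sel])
  pk <- find_peaks(x, prominence_min)
  spread <- unname(diff(quantile(x, c(0.10, 0.40))))
  snr <- if (nrow(pk) == 0L || spread <= 0) NA_real_ else mean(pk$height) / spread
  structure(list(snr = snr, n_peaks = nrow(pk), noise_spread = spread),
            class = "snr_record")
}

#' SNR--performance regression
#'
#' Ordinary least squares of per-cell F1 on per-cell SNR, quantifying how
#' detection performance improves with spike SNR.
#'
#' @param per_cell_f1 numeric vector.
#' @param per_cell_snr numeric vector, same length.
#' @return list: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
snr_performance_regression <- function(per_cell_f1, per_cell_snr) {
  ok <- is.finite(per_cell_f1) & is.finite(per_cell_snr)
  if (sum(ok) < 3L) stop("need at least 3 paired finite observations")
  if (stats::var(per_cell_snr[ok]) == 0) stop("degenerate SNR variance")
  fit <- lm(per_cell_f1[ok] ~ per_cell_snr[ok])
  s <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = s$r.squared,
       p_value = unname(pf(s$fstatistic[1L], s$fstatistic[2L],
                           s$fstatistic[3L], lower.tail = FALSE)),
       n = sum(ok))
}

#' Percentile bootstrap confidence interval
#'
#' @param x numeric vector of per-cell statistics.
#' @param stat summary function (default [median()]).
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param rng_seed optional integer seed.
#' @return list: `estimate`, `lower`, `upper`, `conf`, `n_boot`.
#' @export
bootstrap_ci <- function(x, stat = median, n_boot = 2000, conf = 0.95,
                         rng_seed = NULL) {
  x <- x[is.finite(x)]
  stopifnot(length(x) >= 2L)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  boots <- vapply(seq_len(n_boot),
                  function(i) stat(sample(x, replace = TRUE)), numeric(1L))
  alpha <- (1 - conf) / 2
  list(estimate = stat(x),
       lower = unname(quantile(boots, alpha)),
       upper = unname(quantile(boots, 1 - alpha)),
       conf = conf, n_boot = n_boot)
}

#' Per-cell F1 scores against ground-truth labels
#'
#' Scores a recruitment table (from [detect_recruitment()]) against per-cell
#' label times for one event type, returning one F1 per cell.
#'
#' @param recruitment recruitment data.frame.
#' @param truth_labels data.frame with columns `cell`, `time` of true per-cell
#'   event times.
#' @param event_type event type to score (default `"pis"`).
#' @param tol matching tolerance, seconds (default 1).
#' @param cells cells to score; default all cells present in either table.
#' @return data.frame: `cell`, `tp`, `fp`, `fn`, `f1`.
#' @export
per_cell_f1 <- function(recruitment, truth_labels, event_type = "pis",
                        tol = 1, cells = NULL) {
  rec <- recruitment[recruitment$event_type == event_type &
                       recruitment$recruited, , drop = FALSE]
  if (is.null(cells)) {
    cells <- sort(union(unique(rec$cell), unique(truth_labels$cell)))
  }
  rows <- lapply(cells, function(ci) {
    man <- sort(truth_labels$time[truth_labels$cell == ci])
    det <- sort(rec$recruitment_time[rec$cell == ci])
    if (length(man) == 0L && length(det) == 0L) {
      return(data.frame(cell = ci, tp = 0L, fp = 0L, fn = 0L, f1 = NA_real_))
    }
    mc <- match_events(man, det, tol)
    data.frame(cell = ci, tp = mc$tp, fp = mc$fp, fn = mc$fn,
               f1 = f1_score(mc))
  })
  do.call(rbind, rows)
}
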