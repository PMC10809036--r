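# Independent oracles kept deliberately separate from the implementation paths
# they check.

# Brute-force optimal one-to-one event matching (exhaustive recursion; only
# for tiny inputs). Returns the maximum number of matched pairs within tol.
bf_max_matches <- function(manual, detected, tol = 1) {
  rec <- function(mi, used) {
    if (mi > length(manual)) return(0L)
    best <- rec(mi + 1L, used)            # leave manual[mi] unmatched
    for (j in seq_along(detected)) {
      if (!used[j] && abs(manual[mi] - detected[j]) <= tol) {
        u <- used; u[j] <- TRUE
        best <- max(best, 1L + rec(mi + 1L, u))
      }
    }
    best
  }
  rec(1L, rep(FALSE, length(detected)))
}

# Brute-force slope segments by direct first-difference accumulation.
bf_slope_integrals <- function(x) {
  d <- diff(x)
  out <- numeric(0)
  acc <- 0
  in_run <- FALSE
  for (v in d) {
    if (v > 0) {
      acc <- acc + v
      in_run <- TRUE
    } else if (in_run) {
      out <- c(out, acc)
      acc <- 0
      in_run <- FALSE
    }
  }
  if (in_run) out <- c(out, acc)
  out
}

# Cached small simulations shared across test files (generation is seeded and
# deterministic, caching only saves time).
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, generate_recording(cfg), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

noise_free_cfg <- function(...) {
  sim_config(n_cells = 20, noise_sd = 0, shared_noise_sd = 0, drift_amp = 0,
             rng_seed = 3, ...)
}

# Truth participation/label lookup per detected seed: maps each detected
# population spike seed to the nearest planted population event (pre-ictal
# spike or sentinel) and returns, per cell x seed, the planted participation
# flag and the ideal label time.
truth_by_seed <- function(sim, seed_times) {
  tp <- sim$truth$population_spike_times
  ev <- sim$truth$cell_events
  ev <- ev[ev$event_type %in% c("pis", "sentinel"), ]
  sent <- sim$truth$sentinel_time
  rows <- lapply(seq_along(seed_times), function(k) {
    j <- which.min(abs(tp - seed_times[k]))
    is_sent <- !is.na(sent) && isTRUE(all.equal(tp[j], sent))
    sel <- if (is_sent) ev$event_type == "sentinel" else
      ev$event_type == "pis" & abs(ev$planted_time - tp[j]) < 1
    data.frame(seed_index = k, seed_time = seed_times[k],
               truth_time = tp[j], cell = ev$cell[sel],
               participating = ev$participating[sel],
               label_time = ev$label_time[sel])
  })
  do.call(rbind, rows)
}
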