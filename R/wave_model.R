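#' Fit a traveling-wave plane to recruitment times
#'
#' Models per-cell recruitment times as a plane over the imaged field,
#' `t = b0 + bx*x + by*y`, minimizing the mean squared residual with an L1
#' penalty `lambda * (|bx| + |by|)` on the spatial gradient (the intercept is
#' unpenalized). For a planar traveling wave the time gradient is the slowness
#' vector: propagation speed is `1 / ||(bx, by)||` (micrometers per second for
#' positions in micrometers) and the propagation direction is the gradient
#' direction (times increase along propagation), reported counter-clockwise
#' from the +x axis in degrees.
#'
#' `l1_lambda = "auto"` selects the penalty by 5-fold cross-validation over
#' glmnet's logarithmic grid, falling back to `lambda = 0` (ordinary least
#' squares) when fewer than 10 cells are available.
#'
#' @param times per-cell recruitment times, seconds.
#' @param positions matrix/data.frame of (x, y) positions, micrometers.
#' @param l1_lambda nonnegative penalty, or `"auto"` (default 0).
#' @return list of class `wave_fit`: `beta0`, `gradient` (s/um), `velocity`
#'   (um/s), `angle` (degrees in \[0, 360)), `residual_rss` (s^2), `lambda`,
#'   `n_cells`, and `p_value` (`NA` until [shuffle_test()] is run; forced to 1
#'   for a zero gradient).
#' @export
fit_plane <- function(times, positions, l1_lambda = 0) {
  positions <- as.matrix(positions)[, 1:2, drop = FALSE]
  ok <- is.finite(times) & is.finite(positions[, 1L]) & is.finite(positions[, 2L])
  t_ok <- times[ok]
  xy <- positions[ok, , drop = FALSE]
  n <- length(t_ok)
  if (n < 3L) stop("fit_plane: need at least 3 recruited cells with finite times")
  if (qr(cbind(1, xy))$rank < 3L) stop("fit_plane: positions are collinear")

  if (identical(l1_lambda, "auto")) {
    l1_lambda <- if (n < 10L) {
      0
    } else {
      cv <- glmnet::cv.glmnet(xy, t_ok, alpha = 1, nfolds = 5,
                              standardize = TRUE)
      cv$lambda.min
    }
  }
  if (l1_lambda == 0) {
    fit <- lm(t_ok ~ xy)
    beta <- unname(coef(fit))
  } else {
    g <- glmnet::glmnet(xy, t_ok, alpha = 1, lambda = l1_lambda,
                        standardize = TRUE)
    beta <- as.numeric(coef(g))
  }
  b0 <- beta[1L]
  grad <- beta[2:3]
  gnorm <- sqrt(sum(grad^2))
  resid <- t_ok - (b0 + xy %*% grad)
  rss <- sum(resid^2)
  velocity <- if (gnorm > 0) 1 / gnorm else NA_real_
  angle <- if (gnorm > 0) (atan2(grad[2L], grad[1L]) * 180 / pi) %% 360 else NA_real_
  structure(
    list(beta0 = b0, gradient = grad, velocity = velocity, angle = angle,
         residual_rss = rss, lambda = l1_lambda, n_cells = n,
         p_value = if (gnorm > 0) NA_real_ else 1),
    class = "wave_fit"
  )
}

#' @export
print.wave_fit <- function(x, ...) {
  cat(sprintf("<wave_fit> %d cells: velocity %.4g um/s, angle %.4g deg, RSS %.4g s^2, lambda %.3g, p %s\n",
              x$n_cells, x$velocity, x$angle, x$residual_rss, x$lambda,
              format(x$p_value)))
  invisible(x)
}

refit_rss <- function(times, xy, l1_lambda) {
  if (l1_lambda == 0) {
    f <- stats::.lm.fit(cbind(1, xy), times)
    sum(f$residuals^2)
  } else {
    g <- glmnet::glmnet(xy, times, alpha = 1, lambda = l1_lambda,
                        standardize = TRUE)
    beta <- as.numeric(coef(g))
    sum((times - (beta[1L] + xy %*% beta[2:3]))^2)
  }
}

#' Spatial-shuffle significance test for a wave fit
#'
#' Permutes recruitment times across cell positions, refits the plane with the
#' observed fit's penalty, and compares residual sums of squares:
#' `p = (1 + #\{shuffled RSS <= observed RSS\}) / (1 + n_shuffles)`
#' (add-one permutation rule, so the smallest attainable p is
#' `1/(n_shuffles+1)`).
#'
#' @param times per-cell recruitment times, seconds.
#' @param positions (x, y) positions, micrometers.
#' @param n_shuffles number of permutations (default 1000).
#' @param l1_lambda penalty used for the observed fit and all refits
#'   (default 0); `"auto"` selects once on the observed data.
#' @param rng_seed optional integer seed.
#' @return The observed `wave_fit` with `p_value` filled in.
#' @export
shuffle_test <- function(times, positions, n_shuffles = 1000, l1_lambda = 0,
                         rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  fit <- fit_plane(times, positions, l1_lambda)
  positions <- as.matrix(positions)[, 1:2, drop = FALSE]
  ok <- is.finite(times) & is.finite(positions[, 1L]) & is.finite(positions[, 2L])
  t_ok <- times[ok]
  xy <- positions[ok, , drop = FALSE]
  rss_obs <- fit$residual_rss
  hits <- 0L
  for (i in seq_len(n_shuffles)) {
    rss_i <- refit_rss(sample(t_ok), xy, fit$lambda)
    if (rss_i <= rss_obs) hits <- hits + 1L
  }
  fit$p_value <- (1 + hits) / (1 + n_shuffles)
  fit$n_shuffles <- n_shuffles
  fit
}
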