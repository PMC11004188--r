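#' Across-trial ensemble variance
#'
#' Computes, at every time step, the unbiased (N-1 denominator) variance of
#' position across the trials of an origin-aligned ensemble:
#' sigma^2(t) = 1/(N-1) * sum_i (x(i,t) - mean_j x(j,t))^2.
#'
#' @param ensemble a [trajectory_ensemble()] with at least 2 trials.
#' @return An object of class `variance_curve` with fields `time`, `variance`
#'   and `n_trials`.
#' @examples
#' e <- trajectory_ensemble(0:3, rbind(0:3, -(0:3)))
#' ensemble_variance(e)$variance  # 2 * t^2
#' @export
ensemble_variance <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  n <- nrow(ensemble$positions)
  if (n < 2) stop("ensemble variance requires at least 2 trials")
  mu <- colMeans(ensemble$positions)
  v <- colSums((ensemble$positions - rep(mu, each = n))^2) / (n - 1)
  structure(list(time = ensemble$time, variance = v, n_trials = n),
            class = "variance_curve")
}

#' @export
print.variance_curve <- function(x, ...) {
  cat(sprintf("Ensemble variance curve: %d trials, %d samples, final variance %.4g\n",
              x$n_trials, length(x$time), x$variance[length(x$variance)]))
  invisible(x)
}

#' Linear fit of variance growth
#'
#' Ordinary least squares of ensemble variance against time over a window; a
#' linearly growing variance (R^2 near 1) is the time-domain signature of a
#' Brownian process, and the slope estimates its diffusion coefficient.
#'
#' @param curve a `variance_curve` from [ensemble_variance()].
#' @param window `c(t_start, t_end)` in seconds; default the whole record.
#' @return An object of class `linear_growth_fit`: `slope` (units^2/s),
#'   `intercept`, `r_squared` (clamped to `[0, 1]`), `window`, and `degenerate`
#'   (`TRUE` when the curve is constant over the window).
#' @export
fit_variance_growth <- function(curve, window = range(curve$time)) {
  stopifnot(inherits(curve, "variance_curve"), length(window) == 2)
  sel <- curve$time >= window[1] & curve$time <= window[2]
  if (sum(sel) < 10) stop("variance-fit window must contain at least 10 samples")
  t <- curve$time[sel]
  v <- curve$variance[sel]
  sst <- sum((v - mean(v))^2)
  if (sst < .Machine$double.eps * max(1, mean(v)^2)) {
    return(structure(list(slope = 0, intercept = mean(v), r_squared = 0,
                          window = window, degenerate = TRUE),
                     class = "linear_growth_fit"))
  }
  fit <- lm(v ~ t)
  r2 <- max(0, min(1, suppressWarnings(summary(fit))$r.squared))
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = r2, window = window, degenerate = FALSE),
            class = "linear_growth_fit")
}

#' @export
print.linear_growth_fit <- function(x, ...) {
  cat(sprintf("Variance growth fit over [%.4g, %.4g] s: slope %.4g units^2/s, R^2 = %.3f\n",
              x$window[1], x$window[2], x$slope, x$r_squared))
  invisible(x)
}

#' Breakpoint between linear variance growth and a plateau
#'
#' Fits a continuous two-segment model to the ensemble-variance curve -- a
#' linear ramp up to a break time followed by a constant level -- by
#' exhaustive grid search over candidate break times, minimizing total squared
#' error (for each candidate the ramp is an OLS fit on the folded regressor
#' `min(t, t_bp)`). A BIC comparison against the plain one-segment linear fit
#' guards against spurious plateaus: when the single line wins, `t_bp` is set
#' to the end of the record and `plateau` is `FALSE`. Candidates earlier than
#' the first time the variance exceeds 5% of its final level are excluded.
#'
#' @param curve a `variance_curve` spanning at least 20 s.
#' @param n_grid number of candidate break times to scan.
#' @return An object of class `breakpoint_fit`: `t_bp` (s), `pre_slope`
#'   (units^2/s), `post_level` (units^2), `fit_quality` (R^2 of the selected
#'   model) and `plateau` (logical).
#' @export
detect_breakpoint <- function(curve, n_grid = 200) {
  stopifnot(inherits(curve, "variance_curve"))
  t <- curve$time
  v <- curve$variance
  if (max(t) - min(t) < 20) stop("breakpoint detection requires a curve spanning >= 20 s")
  n <- length(t)

  final_level <- mean(v[t >= max(t) - 0.05 * diff(range(t))])
  t_min <- t[which(v > 0.05 * final_level)[1]]
  if (is.na(t_min)) t_min <- t[2]
  cand <- t[t > t_min & t < max(t)]
  if (length(cand) > n_grid)
    cand <- cand[unique(round(seq(1, length(cand), length.out = n_grid)))]

  sst <- sum((v - mean(v))^2)
  one <- lm(v ~ t)
  sse1 <- sum(one$residuals^2)

  best <- list(sse = Inf, t_bp = NA_real_, slope = NA_real_, icpt = NA_real_)
  for (tb in cand) {
    u <- pmin(t, tb)
    f <- lm.fit(cbind(1, u), v)
    sse <- sum(f$residuals^2)
    if (sse < best$sse)
      best <- list(sse = sse, t_bp = tb, slope = f$coefficients[2],
                   icpt = f$coefficients[1])
  }

  # BIC-style comparison: 2 parameters for the line, 3 for ramp+plateau
  bic1 <- n * log(sse1 / n) + 2 * log(n)
  bic2 <- n * log(best$sse / n) + 3 * log(n)
  if (bic1 <= bic2 || !is.finite(best$t_bp)) {
    structure(list(t_bp = max(t), pre_slope = unname(coef(one)[2]),
                   post_level = NA_real_,
                   fit_quality = max(0, 1 - sse1 / sst), plateau = FALSE),
              class = "breakpoint_fit")
  } else {
    structure(list(t_bp = unname(best$t_bp), pre_slope = unname(best$slope),
                   post_level = unname(best$icpt + best$slope * best$t_bp),
                   fit_quality = max(0, 1 - best$sse / sst), plateau = TRUE),
              class = "breakpoint_fit")
  }
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (x$plateau)
    cat(sprintf("Breakpoint at t_bp = %.4g s; pre-slope %.4g units^2/s, plateau level %.4g (R^2 = %.3f)\n",
                x$t_bp, x$pre_slope, x$post_level, x$fit_quality))
  else
    cat(sprintf("No plateau detected (linear growth throughout; slope %.4g units^2/s)\n",
                x$pre_slope))
  invisible(x)
}
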