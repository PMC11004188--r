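#' Per-trial power spectral density (single-window Welch)
#'
#' Computes each trial's one-sided PSD with Welch's method using the entire
#' trial as one window (a boxcar-tapered periodogram with density scaling), so
#' spectral estimates reach down to the lowest frequency the record allows
#' (1/T). Detrending is either `remove_mean` (subtract each trial's own mean;
#' used for postural data) or `remove_ensemble_mean_trajectory` (subtract the
#' across-trial mean trajectory, removing the common ramp of crank trials).
#'
#' The returned spectra keep all positive-frequency bins (DC is excluded: it
#' is annihilated by detrending); low-bin removal happens in [average_psd()].
#'
#' @param ensemble a [trajectory_ensemble()] (a single trajectory can be
#'   wrapped in a 1-row ensemble with `align = FALSE`).
#' @param detrend `"remove_mean"` or `"remove_ensemble_mean_trajectory"`.
#' @return A list with `frequency` (Hz, positive bins) and `power`
#'   (trials x bins matrix, units^2/Hz).
#' @export
trial_psd <- function(ensemble,
                      detrend = c("remove_mean", "remove_ensemble_mean_trajectory")) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  detrend <- match.arg(detrend)
  x <- ensemble$positions
  if (anyNA(x)) stop("NaN/NA values in the input trajectories")
  n <- ncol(x)
  if (n < 64) stop("trajectories must have at least 64 samples")
  fs <- 1 / mean(diff(ensemble$time))

  if (detrend == "remove_ensemble_mean_trajectory") {
    x <- x - rep(colMeans(x), each = nrow(x))
  } else {
    x <- x - rowMeans(x)
  }

  half <- n %/% 2
  freq <- (1:half) * fs / n
  power <- matrix(NA_real_, nrow(x), half)
  for (i in seq_len(nrow(x))) {
    X <- fft(x[i, ])
    p <- Mod(X[2:(half + 1)])^2 / (fs * n)
    # one-sided density: double all interior bins (Nyquist, if present, is not)
    if (n %% 2 == 0) p[-half] <- 2 * p[-half] else p <- 2 * p
    power[i, ] <- p
  }
  list(frequency = freq, power = power, fs = fs, n_samples = n)
}

#' Trial-averaged PSD with low-bin removal
#'
#' Averages per-trial PSDs arithmetically (in linear power) at each frequency
#' and removes the three lowest frequency points, which depend sensitively on
#' the detrending choices; with a record of length T the lowest retained
#' frequency is therefore 4/T.
#'
#' @param psds the list returned by [trial_psd()] (all trials share one grid).
#' @param drop_low_bins number of lowest bins to remove (default 3).
#' @return An object of class `psd_estimate`: `frequency`, `power` (the
#'   trial-averaged density), `per_trial` matrix, `n_trials`,
#'   `dropped_low_bins`.
#' @export
average_psd <- function(psds, drop_low_bins = 3) {
  stopifnot(is.list(psds), !is.null(psds$frequency), !is.null(psds$power))
  if (ncol(psds$power) != length(psds$frequency))
    stop("per-trial PSDs do not share the frequency grid")
  keep <- seq_along(psds$frequency) > drop_low_bins
  structure(list(frequency = psds$frequency[keep],
                 power = colMeans(psds$power[, keep, drop = FALSE]),
                 per_trial = psds$power[, keep, drop = FALSE],
                 n_trials = nrow(psds$power),
                 dropped_low_bins = drop_low_bins),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("Trial-averaged PSD: %d trials, %d bins in [%.4g, %.4g] Hz (%d low bins dropped)\n",
              x$n_trials, length(x$frequency), min(x$frequency),
              max(x$frequency), x$dropped_low_bins))
  invisible(x)
}

#' Log-log slope of a PSD in dB/decade
#'
#' Ordinary least squares of `10*log10(power)` on `log10(frequency)` over the
#' bins inside `band`. With this power-dB convention a Brownian (1/f^2)
#' process has a slope of exactly -20 dB/decade, and n-fold integrated white
#' noise -20*n. The 95% confidence interval is the classical t-interval on
#' the regression slope.
#'
#' @param psd a `psd_estimate` from [average_psd()], or any list with
#'   `frequency` and `power` vectors.
#' @param band `c(f_min, f_max)` in Hz.
#' @return An object of class `slope_fit`: `slope_db_per_decade`, `ci95`,
#'   `r_squared`, `band`, `n_points`.
#' @examples
#' f <- seq(0.01, 1, by = 0.01)
#' fit_psd_slope(list(frequency = f, power = f^-2), c(0.01, 1))  # -20 dB/dec
#' @export
fit_psd_slope <- function(psd, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  f <- psd$frequency
  p <- psd$power
  sel <- f >= band[1] & f <= band[2]
  if (any(sel & p <= 0)) {
    warning("zero-power bins inside the band were excluded from the slope fit")
    sel <- sel & p > 0
  }
  if (sum(sel) < 3) stop("slope fit requires at least 3 retained bins inside the band")
  lf <- log10(f[sel])
  lp <- 10 * log10(p[sel])
  fit <- lm(lp ~ lf)
  sm <- suppressWarnings(summary(fit))  # exact power laws fit perfectly
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  tcrit <- qt(0.975, df = fit$df.residual)
  structure(list(slope_db_per_decade = slope,
                 ci95 = c(slope - tcrit * se, slope + tcrit * se),
                 r_squared = sm$r.squared,
                 band = band, n_points = sum(sel)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("PSD slope %.2f dB/dec, 95%% CI [%.2f, %.2f], R^2 = %.3f over %g-%g Hz (%d bins)\n",
              x$slope_db_per_decade, x$ci95[1], x$ci95[2], x$r_squared,
              x$band[1], x$band[2], x$n_points))
  invisible(x)
}

#' Full PSD pipeline for an ensemble
#'
#' Convenience wrapper: [trial_psd()] then [average_psd()] then
#' [fit_psd_slope()].
#'
#' @inheritParams trial_psd
#' @inheritParams fit_psd_slope
#' @return A list with `psd` (the `psd_estimate`) and `slope` (the
#'   `slope_fit`).
#' @export
psd_pipeline <- function(ensemble, band,
                         detrend = c("remove_mean", "remove_ensemble_mean_trajectory")) {
  detrend <- match.arg(detrend)
  est <- average_psd(trial_psd(ensemble, detrend))
  list(psd = est, slope = fit_psd_slope(est, band))
}
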