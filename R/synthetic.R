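#' Reference stochastic-process specification
#'
#' Describes an ensemble of trajectories with known closed-form stochastic
#' structure, used as analysis oracles:
#' \describe{
#'   \item{`wiener`}{cumulative sum of iid Gaussian increments of standard
#'     deviation `diffusion_sd * sqrt(dt)`; variance grows as
#'     `diffusion_sd^2 * t` and the PSD falls at -20 dB/decade.}
#'   \item{`ornstein_uhlenbeck`}{mean-reverting diffusion with rate
#'     `reversion_rate` (exact AR(1) discretization); bounded analogue of the
#'     Wiener process with a Lorentzian PSD.}
#'   \item{`integrated_noise`}{white noise passed through
#'     `integration_order` cumulative integrations; PSD slope
#'     `-20 * integration_order` dB/decade.}
#'   \item{`bounded_walk`}{Wiener increments plus a threshold-triggered
#'     corrective Gaussian velocity pulse (the intermittent control law acting
#'     directly on the walker), emulating the postural variance plateau.}
#'   \item{`ramp_plus_wiener`}{`ramp_velocity * t` plus a Wiener process,
#'     emulating constant-speed crank trials.}
#' }
#'
#' Increments use the dt-invariant convention `N(0, diffusion_sd^2 * dt)`.
#'
#' @param kind process kind, see above.
#' @param diffusion_sd noise intensity sigma (units/sqrt(s)), > 0.
#' @param reversion_rate mean-reversion rate theta (1/s), OU only.
#' @param integration_order 1, 2 or 3 (`integrated_noise`; 1 is a Wiener
#'   process).
#' @param bound_threshold,reset_gain bounded-walk geometry: the do-nothing
#'   half-width, and the ratio of one pulse's carried displacement to that
#'   half-width.
#' @param ramp_velocity deterministic drift (units/s, `ramp_plus_wiener`).
#' @param duration,dt,n_trials,seed ensemble geometry and reproducibility.
#' @return An object of class `process_spec`.
#' @export
process_spec <- function(kind = c("wiener", "ornstein_uhlenbeck", "integrated_noise",
                                  "bounded_walk", "ramp_plus_wiener"),
                         diffusion_sd = 1,
                         reversion_rate = NULL,
                         integration_order = 1L,
                         bound_threshold = NULL, reset_gain = 1.5,
                         ramp_velocity = NULL,
                         duration = 26, dt = 0.005, n_trials = 200, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(diffusion_sd) || diffusion_sd <= 0) stop("'diffusion_sd' must be > 0")
  if (kind == "ornstein_uhlenbeck" &&
      (is.null(reversion_rate) || reversion_rate <= 0))
    stop("'reversion_rate' (theta) must be > 0 for an OU process")
  if (kind == "integrated_noise" && !(integration_order %in% 1:3))
    stop("'integration_order' must be 1, 2 or 3")
  if (kind == "bounded_walk" &&
      (is.null(bound_threshold) || bound_threshold <= 0))
    stop("'bound_threshold' must be > 0 for a bounded walk")
  if (kind == "ramp_plus_wiener" && is.null(ramp_velocity))
    stop("'ramp_velocity' is required for ramp_plus_wiener")
  if (duration <= 0 || dt <= 0) stop("'duration' and 'dt' must be > 0")
  structure(list(kind = kind, diffusion_sd = diffusion_sd,
                 reversion_rate = reversion_rate,
                 integration_order = as.integer(integration_order),
                 bound_threshold = bound_threshold, reset_gain = reset_gain,
                 ramp_velocity = ramp_velocity,
                 duration = duration, dt = dt,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "process_spec")
}

#' Generate a reference-process ensemble
#'
#' Draws `n_trials` independent trajectories of the process described by
#' `spec`, deterministically per seed, all starting at the origin.
#'
#' @param spec a [process_spec()].
#' @return A [trajectory_ensemble()] with unit label `"units"`.
#' @examples
#' e <- generate_process(process_spec("wiener", duration = 5, n_trials = 20))
#' ensemble_variance(e)$variance[length(e$time)]  # ~ diffusion_sd^2 * 5
#' @export
generate_process <- function(spec) {
  stopifnot(inherits(spec, "process_spec"))
  n_steps <- round(spec$duration / spec$dt)
  tt <- seq(0, by = spec$dt, length.out = n_steps + 1)
  set.seed(spec$seed)
  trial_seeds <- sample.int(.Machine$integer.max, spec$n_trials)
  pos <- matrix(NA_real_, spec$n_trials, n_steps + 1)
  for (i in seq_len(spec$n_trials)) {
    set.seed(trial_seeds[i])
    pos[i, ] <- generate_one(spec, n_steps, tt)
  }
  trajectory_ensemble(tt, pos, units = "units",
                      meta = c(list(trial_seeds = trial_seeds), unclass(spec)))
}

generate_one <- function(spec, n_steps, tt) {
  sig <- spec$diffusion_sd
  dt <- spec$dt
  switch(spec$kind,
    wiener = c(0, cumsum(rnorm(n_steps, 0, sig * sqrt(dt)))),
    ramp_plus_wiener =
      spec$ramp_velocity * tt + c(0, cumsum(rnorm(n_steps, 0, sig * sqrt(dt)))),
    ornstein_uhlenbeck = {
      th <- spec$reversion_rate
      phi <- exp(-th * dt)
      innov_sd <- sig * sqrt((1 - phi^2) / (2 * th))
      x <- numeric(n_steps + 1)
      z <- rnorm(n_steps, 0, innov_sd)
      for (k in seq_len(n_steps)) x[k + 1] <- phi * x[k] + z[k]
      x
    },
    integrated_noise = {
      x <- cumsum(rnorm(n_steps, 0, sig * sqrt(dt)))
      if (spec$integration_order > 1)
        for (j in seq_len(spec$integration_order - 1)) x <- cumsum(x) * dt
      c(0, x)
    },
    bounded_walk = {
      ic <- intermittent_spec(
        threshold = spec$bound_threshold,
        peak_velocity = spec$reset_gain * spec$bound_threshold / (0.1 * sqrt(2 * pi)),
        pulse_sd = 0.1)
      bounded_walk_cpp(rnorm(n_steps, 0, sig * sqrt(dt)), dt,
                       ic$threshold, ic$peak_velocity,
                       ic$pulse_sd, ic$pulse_center_offset)
    })
}

#' Closed-form ensemble variance of a reference process
#'
#' The analytic oracle backing the Monte-Carlo tests: `diffusion_sd^2 * t`
#' for a Wiener process and
#' `diffusion_sd^2 / (2 theta) * (1 - exp(-2 theta t))` for an
#' Ornstein-Uhlenbeck process started at the origin.
#'
#' @param spec a [process_spec()] of kind `wiener` or `ornstein_uhlenbeck`.
#' @param t time (s), vectorized.
#' @return Variance (units^2) at each `t`.
#' @examples
#' closed_form_variance(process_spec("wiener", diffusion_sd = 2), 3)  # 12
#' @export
closed_form_variance <- function(spec, t) {
  stopifnot(inherits(spec, "process_spec"))
  switch(spec$kind,
    wiener = spec$diffusion_sd^2 * t,
    ornstein_uhlenbeck = {
      th <- spec$reversion_rate
      spec$diffusion_sd^2 / (2 * th) * (1 - exp(-2 * th * t))
    },
    stop("closed-form variance is available for 'wiener' and 'ornstein_uhlenbeck' only"))
}
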