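#' Trajectory ensemble container
#'
#' The universal currency between simulation, synthesis and analysis: `N`
#' origin-aligned position trajectories on one uniform time grid.
#'
#' @param time numeric vector of sample times (s), uniform and increasing.
#' @param positions `N x T` matrix, one row per trial.
#' @param units position units label (e.g. `"rad"`).
#' @param meta named list of provenance (task, architecture, seed, parameter
#'   snapshot).
#' @param align if `TRUE` (default) each trial is shifted so its first sample
#'   is exactly 0.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(time, positions, units = "rad",
                                meta = list(), align = TRUE) {
  positions <- as.matrix(positions)
  if (length(time) != ncol(positions))
    stop("'time' length must match the number of columns of 'positions'")
  dts <- diff(time)
  if (any(dts <= 0) || diff(range(dts)) > 1e-9 * mean(dts))
    stop("'time' must be a strictly increasing uniform grid")
  dimnames(positions) <- NULL
  if (align) positions <- positions - positions[, 1]
  structure(list(time = as.numeric(time), positions = positions,
                 units = units, meta = meta),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d trials x %d samples (%.4g s at %.6g Hz), units %s\n",
              nrow(x$positions), ncol(x$positions),
              max(x$time) - min(x$time),
              1 / mean(diff(x$time)), x$units))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trajectory_ensemble <- function(x) dim(x$positions)

# Exact zero-order-hold discretization of dx/dt = A x + B u via the augmented
# matrix exponential (works for singular A, e.g. the arm's pole at the origin).
zoh_discretize <- function(A, B, dt) {
  n <- nrow(A)
  M <- rbind(cbind(A, B), matrix(0, ncol(B), n + ncol(B))) * dt
  E <- as.matrix(Matrix::expm(Matrix::Matrix(M)))
  list(Ad = E[1:n, 1:n, drop = FALSE], Bd = E[1:n, n + 1, drop = FALSE])
}

# Closed-loop characteristic poles ignoring the delay, used for the stability
# and step-size guards. model_ii intentionally places one pole at the origin.
closed_loop_poles <- function(plant, controller) {
  inertia <- plant_inertia(plant)
  kg <- gravity_stiffness(plant)
  if (controller$architecture == "model_ii") {
    polyroot(c(0, plant$damping + controller$velocity_gain, inertia))
  } else {
    polyroot(c(controller$k_c - kg, plant$damping, inertia))
  }
}

validate_loop <- function(plant, controller, task) {
  kg <- gravity_stiffness(plant)
  if (controller$architecture != "model_ii") {
    if (plant$gravity_mode == "gravity_neutral" && controller$k_c <= 0)
      stop("gravity-neutral plant requires k_c > 0")
    if (plant$gravity_mode == "inverted_pendulum" && controller$k_c <= kg)
      stop(sprintf("inverted pendulum requires k_c > mgL = %.4g N m/rad", kg))
  }
  if (controller$architecture == "model_ii" && controller$delay > 0 &&
      controller$velocity_gain >= plant$damping)
    stop("delayed velocity loop unstable: model_ii requires velocity_gain < damping")
  if (!is.null(controller$intermittent)) {
    if (task$task == "crank")
      stop("the crank task does not use the intermittent controller")
    if (controller$architecture != "model_iii")
      stop("the intermittent controller is defined for model_iii only")
  }
  poles <- closed_loop_poles(plant, controller)
  re <- Re(poles)
  tol <- 1e-9
  if (controller$architecture == "model_ii") {
    # one marginal pole at the origin is the architecture's point
    if (any(re > tol & abs(poles) > tol))
      stop("unstable closed loop: pole(s) with positive real part")
  } else if (any(re > tol)) {
    stop(sprintf("unstable closed loop: pole(s) at %s rad/s",
                 paste(format(poles[re > tol], digits = 4), collapse = ", ")))
  }
  fastest <- max(abs(re))
  if (fastest > 0 && task$dt > 0.1 / fastest)
    stop(sprintf("dt = %g s too coarse for fastest closed-loop pole %.4g rad/s (need dt <= %.4g s)",
                 task$dt, fastest, 0.1 / fastest))
  invisible(poles)
}

#' Simulate one trial of the closed-loop model
#'
#' Runs the selected architecture for one trial: the linear plant is advanced
#' with exact zero-order-hold discretization at step `task$dt`, the feedback
#' path applies a pure delay (`controller$delay` seconds as an integer sample
#' buffer, zero-filled at start), and the trajectory is decimated to
#' `task$output_rate`. White-noise samples are drawn per step as
#' `N(0, sigma^2/dt)` so the injected spectra are independent of `dt`.
#'
#' @param plant a [plant_params()] object.
#' @param controller a [controller_spec()].
#' @param task a [task_spec()].
#' @param trial_seed integer seed for this trial's noise streams.
#' @return A list with `time` (s) and `position` at the output rate.
#' @examples
#' tr <- simulate_trial(arm_plant(),
#'                      controller_spec("model_iii", k_c = arm_gain()),
#'                      task_spec("crank", duration = 26), trial_seed = 1)
#' tail(tr$position, 1)  # ~ v_ref * 26 s minus a constant tracking lag
#' @export
simulate_trial <- function(plant, controller, task, trial_seed = 1L) {
  stopifnot(inherits(plant, "plant_params"),
            inherits(controller, "controller_spec"),
            inherits(task, "task_spec"))
  validate_loop(plant, controller, task)

  ss <- make_plant(plant)
  d <- zoh_discretize(ss$A, ss$B, task$dt)
  n_steps <- round(task$duration / task$dt)
  delay_steps <- round(controller$delay / task$dt)
  decim <- round(1 / (task$output_rate * task$dt))

  arch <- match(controller$architecture, c("model_i", "model_ii", "model_iii"))
  kg <- gravity_stiffness(plant)

  set.seed(as.integer(trial_seed))
  noise_w <- if (arch == 3L && controller$noise_velocity_sd > 0)
    rnorm(n_steps, 0, controller$noise_velocity_sd / sqrt(task$dt)) else numeric(n_steps)
  noise_f <- if (controller$noise_force_sd > 0)
    rnorm(n_steps, 0, controller$noise_force_sd / sqrt(task$dt)) else numeric(n_steps)

  ic <- controller$intermittent
  pos <- sim_loop_cpp(d$Ad, as.numeric(d$Bd),
                      n_steps, task$dt, delay_steps,
                      arch,
                      kc = controller$k_c,
                      kv = controller$velocity_gain,
                      cancel_stiffness = if (arch == 2L) kg else 0,
                      v_ref = task$reference_velocity,
                      leak_alpha = if (arch == 1L) task$dt / controller$leak_time_constant else 0,
                      noise_w = noise_w, noise_f = noise_f,
                      has_ic = !is.null(ic),
                      ic_threshold = if (is.null(ic)) 0 else ic$threshold,
                      ic_vmax = if (is.null(ic)) 0 else ic$peak_velocity,
                      ic_c = if (is.null(ic)) 1 else ic$pulse_sd,
                      ic_t0 = if (is.null(ic)) 0 else ic$pulse_center_offset,
                      decim = decim)
  list(time = seq(0, by = 1 / task$output_rate, length.out = length(pos)),
       position = pos)
}

#' Simulate a Monte-Carlo ensemble of trials
#'
#' Runs [simulate_trial()] `task$n_trials` times with per-trial seeds spawned
#' deterministically from `task$seed`, so each trial's noise streams are
#' independent and the whole ensemble is reproducible bit-for-bit from
#' (parameters, seed). Trials are aligned so every first sample is at the
#' origin, and the full parameter snapshot is stored in `meta`.
#'
#' @inheritParams simulate_trial
#' @return A [trajectory_ensemble()].
#' @export
simulate_ensemble <- function(plant, controller, task) {
  if (task$n_trials < 2) stop("'n_trials' must be >= 2")
  set.seed(task$seed)
  trial_seeds <- sample.int(.Machine$integer.max, task$n_trials)
  n_out <- round(task$duration / task$dt) %/%
    round(1 / (task$output_rate * task$dt)) + 1L
  positions <- matrix(NA_real_, task$n_trials, n_out)
  tt <- NULL
  for (i in seq_len(task$n_trials)) {
    tr <- tryCatch(simulate_trial(plant, controller, task, trial_seeds[i]),
                   error = function(e)
                     stop(sprintf("trial %d failed: %s", i, conditionMessage(e)),
                          call. = FALSE))
    positions[i, ] <- tr$position
    tt <- tr$time
  }
  trajectory_ensemble(tt, positions, units = "rad",
                      meta = list(task = task$task,
                                  architecture = controller$architecture,
                                  seed = task$seed,
                                  trial_seeds = trial_seeds,
                                  plant = unclass(plant),
                                  controller = controller_snapshot(controller),
                                  task_spec = unclass(task)))
}

controller_snapshot <- function(controller) {
  out <- unclass(controller)
  if (!is.null(out$intermittent)) out$intermittent <- unclass(out$intermittent)
  out
}
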