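#' Physical parameters of the single-DOF plant
#'
#' Describes the controlled mechanical system as a point mass `mass` at
#' distance `lever_arm` from the joint (moment of inertia `mass * lever_arm^2`;
#' distributed inertia neglected) with viscous damping `damping`. In
#' `"gravity_neutral"` mode the plant is a marginally stable second-order
#' system (gravity acts along the joint axis); in `"inverted_pendulum"` mode a
#' destabilizing gravitational stiffness `mass * g * lever_arm` is added,
#' modelling upright stance about the ankle.
#'
#' @param mass total mass (kg), > 0.
#' @param lever_arm distance from joint to center of mass (m), > 0.
#' @param damping viscous damping coefficient (N m s/rad), >= 0.
#' @param gravity_mode `"gravity_neutral"` or `"inverted_pendulum"`.
#' @param g gravitational acceleration (m/s^2).
#' @return An object of class `plant_params`.
#' @examples
#' arm_plant()
#' plant_params(75, 1, 226, "inverted_pendulum")
#' @export
plant_params <- function(mass, lever_arm, damping,
                         gravity_mode = c("gravity_neutral", "inverted_pendulum"),
                         g = 9.81) {
  gravity_mode <- match.arg(gravity_mode)
  stopifnot(is.numeric(mass), length(mass) == 1L,
            is.numeric(lever_arm), length(lever_arm) == 1L,
            is.numeric(damping), length(damping) == 1L)
  if (!is.finite(mass) || mass <= 0) stop("'mass' must be > 0")
  if (!is.finite(lever_arm) || lever_arm <= 0) stop("'lever_arm' must be > 0")
  if (!is.finite(damping) || damping < 0) stop("'damping' must be >= 0")
  structure(list(mass = mass, lever_arm = lever_arm, damping = damping,
                 gravity_mode = gravity_mode, g = g),
            class = "plant_params")
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Single-DOF plant (", x$gravity_mode, ")\n", sep = "")
  cat(sprintf("  m = %g kg, L = %g m, beta = %g N m s/rad\n",
              x$mass, x$lever_arm, x$damping))
  cat(sprintf("  inertia mL^2 = %g kg m^2", plant_inertia(x)))
  if (x$gravity_mode == "inverted_pendulum")
    cat(sprintf(", gravitational stiffness mgL = %g N m/rad", gravity_stiffness(x)))
  cat("\n")
  invisible(x)
}

#' Moment of inertia and gravitational stiffness of a plant
#'
#' @param params a [plant_params()] object.
#' @return `plant_inertia`: mass * lever_arm^2 (kg m^2). `gravity_stiffness`:
#'   mass * g * lever_arm (N m/rad) in inverted-pendulum mode, 0 otherwise.
#' @export
plant_inertia <- function(params) params$mass * params$lever_arm^2

#' @rdname plant_inertia
#' @export
gravity_stiffness <- function(params) {
  if (params$gravity_mode == "inverted_pendulum")
    params$mass * params$g * params$lever_arm
  else 0
}

#' Default arm and stance plants
#'
#' Published single-DOF parameter sets used throughout: a gravity-neutral arm
#' (m = 1.5 kg, L = 0.35 m, beta = 30 N m s/rad) and an upright-stance inverted
#' pendulum (m = 75 kg, L = 1 m, beta = 226 N m s/rad). The matching default
#' proportional feedback gains are k_c = 65 and k_c = 883 N m/rad; the stance
#' gain exceeds the destabilizing gravitational stiffness mgL = 735.75 N m/rad
#' as closed-loop stability requires.
#'
#' @return A `plant_params` object.
#' @export
arm_plant <- function() plant_params(1.5, 0.35, 30, "gravity_neutral")

#' @rdname arm_plant
#' @export
stance_plant <- function() plant_params(75, 1, 226, "inverted_pendulum")

#' @rdname arm_plant
#' @export
arm_gain <- function() 65

#' @rdname arm_plant
#' @export
stance_gain <- function() 883

#' Continuous-time state-space realization of the plant
#'
#' Builds the two-state (position, velocity) realization whose transfer
#' function from joint torque to position is 1 / (m L^2 s^2 + beta s) in
#' gravity-neutral mode, or 1 / (m L^2 s^2 + beta s - m g L) for the inverted
#' pendulum.
#'
#' @param params a [plant_params()] object.
#' @return An object of class `state_space` with fields `A` (2x2), `B` (2x1),
#'   `C` (1x2), `D`, and `poles` (eigenvalues of `A`).
#' @examples
#' make_plant(arm_plant())$poles     # {0, -beta/(m L^2)}
#' make_plant(stance_plant())$poles  # one positive (unstable) pole
#' @export
make_plant <- function(params) {
  stopifnot(inherits(params, "plant_params"))
  inertia <- plant_inertia(params)
  kg <- gravity_stiffness(params)
  A <- matrix(c(0, kg / inertia, 1, -params$damping / inertia), 2, 2)
  B <- matrix(c(0, 1 / inertia), 2, 1)
  C <- matrix(c(1, 0), 1, 2)
  structure(list(A = A, B = B, C = C, D = 0,
                 poles = eigen(A, only.values = TRUE)$values,
                 params = params),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State-space plant model; poles:",
      paste(format(x$poles, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Intermittent-controller specification
#'
#' Threshold-triggered Gaussian velocity pulses: the controller is silent
#' (do-nothing region) while the measured position stays within
#' `[-threshold, +threshold]` and no pulse is in flight. When the measurement
#' leaves that region a corrective velocity pulse
#' `v(t) = -sgn(x_m) * peak_velocity * exp(-(t - t_c)^2 / (2 pulse_sd^2))`
#' is emitted (sign opposing the displacement, pushing the plant back toward
#' the origin), with center `t_c = t_trigger + pulse_center_offset`. Once
#' triggered, the pulse runs to completion (4 pulse widths past its center)
#' before the threshold is re-assessed.
#'
#' The default `peak_velocity` is sized so the displacement carried by one
#' complete pulse (`peak_velocity * pulse_sd * sqrt(2 pi)`) equals about 1.5
#' thresholds: a single submovement re-enters the do-nothing region without
#' large overshoot.
#'
#' @param threshold do-nothing half-width (position units), > 0.
#' @param peak_velocity pulse peak magnitude (position units/s), > 0.
#' @param pulse_sd Gaussian width c of the pulse (s), > 0.
#' @param pulse_center_offset delay from trigger to pulse center (s); the
#'   default `4 * pulse_sd` lets the pulse ramp up continuously from ~0.
#' @param retrigger_policy only `"complete_pulse_then_reassess"` is defined.
#' @return An object of class `intermittent_spec`.
#' @export
intermittent_spec <- function(threshold,
                              peak_velocity = 1.5 * threshold / (pulse_sd * sqrt(2 * pi)),
                              pulse_sd = 0.1,
                              pulse_center_offset = 4 * pulse_sd,
                              retrigger_policy = "complete_pulse_then_reassess") {
  stopifnot(identical(retrigger_policy, "complete_pulse_then_reassess"))
  if (!is.numeric(threshold) || threshold <= 0) stop("'threshold' must be > 0")
  if (!is.numeric(peak_velocity) || peak_velocity <= 0) stop("'peak_velocity' must be > 0")
  if (!is.numeric(pulse_sd) || pulse_sd <= 0) stop("'pulse_sd' must be > 0")
  structure(list(threshold = threshold, peak_velocity = peak_velocity,
                 pulse_sd = pulse_sd, pulse_center_offset = pulse_center_offset,
                 retrigger_policy = retrigger_policy),
            class = "intermittent_spec")
}

#' Controller architecture specification
#'
#' Selects one of the three rival closed-loop architectures and its gains:
#' \describe{
#'   \item{`model_i`}{position feedback `k_c` with a noiseless position
#'     reference; the torque disturbance is white noise shaped by a first-order
#'     leaky integrator (unity DC gain, time constant `leak_time_constant`).}
#'   \item{`model_ii`}{net closed-loop stiffness is forced to zero (free
#'     integrator in the closed loop): the gravitational stiffness is cancelled
#'     exactly for stance and no position feedback is used for the arm.
#'     Velocity is tracked by proportional velocity feedback `velocity_gain`
#'     with no integral action; white torque noise enters at the plant input.}
#'   \item{`model_iii`}{position feedback `k_c` around a reference generated by
#'     integrating a forward-path velocity command corrupted by white noise
#'     (`noise_velocity_sd`), plus white torque noise (`noise_force_sd`);
#'     optionally a threshold-triggered intermittent controller adds
#'     corrective velocity pulses to the forward path.}
#' }
#'
#' Noise strengths are continuous-time intensities: a white signal of strength
#' `sigma` contributes discrete samples `N(0, sigma^2/dt)` at step `dt`,
#' equivalently random-walk increments of variance `sigma^2 * dt`, so the
#' simulated spectra do not depend on the integration step.
#'
#' @param architecture `"model_i"`, `"model_ii"` or `"model_iii"`.
#' @param k_c proportional position gain (N m/rad). Must be > 0
#'   (gravity-neutral) or > mgL (inverted pendulum); ignored for `model_ii`,
#'   which overrides it to cancel net stiffness.
#' @param delay sensor feedback delay (s), default 0.100.
#' @param leak_time_constant leaky-integrator time constant (s), `model_i` only.
#' @param noise_force_sd torque white-noise intensity (N m sqrt(s)).
#' @param noise_velocity_sd velocity-command white-noise intensity
#'   (rad/sqrt(s)); `model_iii` only.
#' @param intermittent an [intermittent_spec()] or `NULL`.
#' @param velocity_gain proportional velocity-feedback gain (N m s/rad) used by
#'   `model_ii` to track a velocity reference without integral action. Must
#'   stay below the plant damping when the feedback is delayed: `k_v < beta`
#'   keeps the delayed velocity loop's gain below unity at all frequencies, so
#'   it is stable for any delay (a larger gain sends the loop crossover far
#'   beyond the delay's phase limit).
#' @return An object of class `controller_spec`.
#' @export
controller_spec <- function(architecture = c("model_iii", "model_i", "model_ii"),
                            k_c = arm_gain(),
                            delay = 0.100,
                            leak_time_constant = NULL,
                            noise_force_sd = 0,
                            noise_velocity_sd = 0,
                            intermittent = NULL,
                            velocity_gain = 20) {
  architecture <- match.arg(architecture)
  if (!is.numeric(delay) || delay < 0) stop("'delay' must be >= 0")
  if (!is.numeric(noise_force_sd) || noise_force_sd < 0)
    stop("'noise_force_sd' must be >= 0")
  if (!is.numeric(noise_velocity_sd) || noise_velocity_sd < 0)
    stop("'noise_velocity_sd' must be >= 0")
  if (architecture == "model_i") {
    if (is.null(leak_time_constant) || leak_time_constant <= 0)
      stop("'leak_time_constant' must be > 0 for model_i")
  } else if (!is.null(leak_time_constant)) {
    stop("'leak_time_constant' is only meaningful for model_i")
  }
  if (!is.null(intermittent) && !inherits(intermittent, "intermittent_spec"))
    stop("'intermittent' must be an intermittent_spec or NULL")
  structure(list(architecture = architecture, k_c = k_c, delay = delay,
                 leak_time_constant = leak_time_constant,
                 noise_force_sd = noise_force_sd,
                 noise_velocity_sd = noise_velocity_sd,
                 intermittent = intermittent,
                 velocity_gain = velocity_gain),
            class = "controller_spec")
}

#' Motor-task specification
#'
#' @param task `"crank"` (constant-velocity turning), `"hand_posture"` or
#'   `"quiet_standing"` (both postural: zero reference velocity).
#' @param reference_velocity constant reference speed (rad/s); must be nonzero
#'   for `crank` and zero for postural tasks. Default for crank: 0.075 rev/s =
#'   0.4712 rad/s.
#' @param duration simulated time (s).
#' @param dt internal integration step (s); `1/(output_rate * dt)` must be a
#'   whole number.
#' @param output_rate sampling rate of the recorded trajectory (Hz).
#' @param n_trials ensemble size.
#' @param seed integer master seed for the ensemble.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(task = c("crank", "hand_posture", "quiet_standing"),
                      reference_velocity = if (task == "crank") 0.075 * 2 * pi else 0,
                      duration = 400,
                      dt = 5e-4,
                      output_rate = 100,
                      n_trials = 200,
                      seed = 1L) {
  task <- match.arg(task)
  if (task == "crank" && reference_velocity == 0)
    stop("crank task requires a nonzero 'reference_velocity'")
  if (task != "crank" && reference_velocity != 0)
    stop("postural tasks require 'reference_velocity' = 0")
  if (duration <= 0 || dt <= 0) stop("'duration' and 'dt' must be > 0")
  decim <- 1 / (output_rate * dt)
  if (abs(decim - round(decim)) > 1e-8)
    stop("1/(output_rate * dt) must be an integer decimation factor")
  structure(list(task = task, reference_velocity = reference_velocity,
                 duration = duration, dt = dt, output_rate = output_rate,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "task_spec")
}
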