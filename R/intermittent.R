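#' Evaluate the intermittent corrective velocity command
#'
#' One step of the threshold-triggered intermittent controller: returns the
#' corrective velocity at time `clock` given the current position measurement
#' and the pulse-in-flight state, together with the updated state. The command
#' is 0 whenever the measurement lies inside the do-nothing region
#' `[-threshold, threshold]` and no pulse is in flight. Crossing the threshold
#' triggers a Gaussian velocity pulse centered `pulse_center_offset` seconds
#' after the trigger, with sign opposing the displacement; the pulse runs to
#' completion (4 pulse widths past its center) before the threshold is
#' re-assessed.
#'
#' This is a total function of its inputs: it never errors and performs no
#' I/O, so it can be driven by any caller (the closed-loop simulator and the
#' bounded-walk generator both use this law).
#'
#' @param x_measured measured position (same units as `spec$threshold`).
#' @param clock current time (s).
#' @param state pulse-in-flight record as returned by a previous call, or
#'   `NULL` at start.
#' @param spec an [intermittent_spec()].
#' @return A list with `velocity` (the commanded corrective velocity) and
#'   `state` (record to pass to the next call: `active`, `t_trigger`, `sign`).
#' @examples
#' sp <- intermittent_spec(threshold = 0.05)
#' intermittent_command(0.02, 0, NULL, sp)$velocity  # inside region: 0
#' @export
intermittent_command <- function(x_measured, clock, state, spec) {
  stopifnot(inherits(spec, "intermittent_spec"))
  if (is.null(state)) state <- list(active = FALSE, t_trigger = NA_real_, sign = 0)
  if (isTRUE(state$active)) {
    tc <- state$t_trigger + spec$pulse_center_offset
    if (clock <= tc + 4 * spec$pulse_sd) {
      v <- -state$sign * spec$peak_velocity *
        exp(-(clock - tc)^2 / (2 * spec$pulse_sd^2))
      return(list(velocity = v, state = state))
    }
    state$active <- FALSE
  }
  if (abs(x_measured) > spec$threshold) {
    state <- list(active = TRUE, t_trigger = clock,
                  sign = if (x_measured > 0) 1 else -1)
    tc <- clock + spec$pulse_center_offset
    v <- -state$sign * spec$peak_velocity *
      exp(-(clock - tc)^2 / (2 * spec$pulse_sd^2))
    return(list(velocity = v, state = state))
  }
  list(velocity = 0, state = state)
}
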