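#' Homeostatic alpha-amplitude plant state
#'
#' A two-state stochastic relaxation model of session-level alpha amplitude
#' at the feedback site. `alpha_current` is the momentary amplitude;
#' `alpha_setpoint` is the homeostatic equilibrium it relaxes toward. Reward-
#' contingent down-training pushes `alpha_current` below the setpoint; while
#' suppression is applied the setpoint itself drifts upward at
#' `homeostatic_gain`, so that after training ends the amplitude relaxes to a
#' raised equilibrium. This is the simplest mechanism that produces both the
#' within-session return toward baseline and the pre-to-post resting "alpha
#' rebound".
#'
#' @param alpha_setpoint equilibrium amplitude, uV (>= 0).
#' @param alpha_current momentary amplitude, uV (>= 0); defaults to the
#'   setpoint.
#' @param homeostatic_gain upward setpoint drift per minute of full
#'   suppression drive, uV/min (>= 0).
#' @param suppression_gain fractional down-pull per minute at full drive
#'   (>= 0, dimensionless rate).
#' @param relax_rate relaxation rate toward the setpoint, 1/min (> 0).
#' @param noise_sd amplitude noise SD per sqrt(second), uV (>= 0).
#'
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(alpha_setpoint = 10, alpha_current = alpha_setpoint,
                        homeostatic_gain = 0, suppression_gain = 0,
                        relax_rate = 2, noise_sd = 0) {
  stopifnot(alpha_setpoint >= 0, alpha_current >= 0,
            homeostatic_gain >= 0, suppression_gain >= 0,
            relax_rate > 0, noise_sd >= 0)
  structure(
    list(alpha_setpoint = alpha_setpoint, alpha_current = alpha_current,
         homeostatic_gain = homeostatic_gain,
         suppression_gain = suppression_gain,
         relax_rate = relax_rate, noise_sd = noise_sd),
    class = "plant_state")
}

#' Advance the alpha plant by one time step
#'
#' Euler step of the two-state model: the current amplitude relaxes toward
#' the setpoint at `relax_rate`, is pulled down proportionally to
#' `suppression_gain * drive`, and receives additive Gaussian noise scaled by
#' `sqrt(dt)`; the setpoint drifts up by `homeostatic_gain * drive * dt`.
#' Both states are clamped at zero.
#'
#' @param state a [plant_state()].
#' @param drive suppression drive in \[0, 1\] (fraction of full down-training
#'   pressure for this step).
#' @param dt step duration in seconds (> 0).
#'
#' @return The updated `plant_state`.
#' @export
#' @examples
#' st <- plant_state(10, 14, relax_rate = 6)
#' for (i in 1:100) st <- plant_step(st, 0, 0.4)
#' st$alpha_current # ~10
plant_step <- function(state, drive, dt) {
  stopifnot(inherits(state, "plant_state"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a positive scalar", call. = FALSE)
  }
  stopifnot(is.numeric(drive), length(drive) == 1L, drive >= 0, drive <= 1)
  dtm <- dt / 60 # gains are per minute
  cur <- state$alpha_current
  cur <- cur +
    state$relax_rate * dtm * (state$alpha_setpoint - cur) -
    state$suppression_gain * dtm * drive * cur
  if (state$noise_sd > 0) cur <- cur + rnorm(1, 0, state$noise_sd * sqrt(dt))
  state$alpha_current <- max(cur, 0)
  state$alpha_setpoint <- max(
    state$alpha_setpoint + state$homeostatic_gain * dtm * drive, 0)
  state
}
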