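#' Movement parameters
#'
#' Correlated-random-walk settings shared by the active predator and the
#' mobile prey. Each move turns the agent by a uniform draw on
#' `[-max_turn, +max_turn]` degrees and advances it `step_length` cells along
#' the new heading. Directional movement uses a small maximum turn (10
#' degrees), nondirectional movement a large one (120 degrees). A speed
#' multiplier of 2 is implemented as two unit sub-steps per time step, each
#' followed by a capture check, so a fast mover cannot tunnel through a cell.
#'
#' @param directional_max_turn Maximum turn (degrees) in directional mode.
#' @param nondirectional_max_turn Maximum turn (degrees) in nondirectional
#'   mode (also the turn used while the area-restricted-search timer runs).
#' @param step_length Distance moved per sub-step, in cells.
#' @param speed_multiplier_active,speed_multiplier_mobile Unit sub-steps per
#'   time step (1 or 2) for the active predator and the mobile prey.
#' @return An object of class `movement_params`.
#' @export
movement_params <- function(directional_max_turn = 10,
                            nondirectional_max_turn = 120,
                            step_length = 1,
                            speed_multiplier_active = 1L,
                            speed_multiplier_mobile = 1L) {
  .check_turn(directional_max_turn)
  .check_turn(nondirectional_max_turn)
  if (step_length <= 0) stop("step_length must be positive", call. = FALSE)
  .check_mult(speed_multiplier_active, "speed_multiplier_active")
  .check_mult(speed_multiplier_mobile, "speed_multiplier_mobile")
  structure(list(directional_max_turn = as.numeric(directional_max_turn),
                 nondirectional_max_turn = as.numeric(nondirectional_max_turn),
                 step_length = as.numeric(step_length),
                 speed_multiplier_active = as.integer(speed_multiplier_active),
                 speed_multiplier_mobile = as.integer(speed_multiplier_mobile)),
            class = "movement_params")
}

.check_turn <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 180) {
    stop("max turn angles must lie in [0, 180] degrees", call. = FALSE)
  }
}

.check_mult <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || x < 1 || x != round(x)) {
    stop(name, " must be a positive integer", call. = FALSE)
  }
}

#' Area-restricted search parameters
#'
#' After the active predator encounters a sedentary prey it switches from
#' directional to nondirectional turning for `duration` time steps; a further
#' encounter during that window resets the countdown to the full duration
#' (it is not additive). The trigger is cell co-occupancy with a sedentary
#' prey by default (`"on_encounter"`); `"on_capture"` restricts triggering to
#' successful captures, which differs only under uncertain (50%) capture.
#'
#' @param enabled Is ARS active for the predator?
#' @param duration Countdown length in time steps.
#' @param trigger `"on_encounter"` or `"on_capture"`.
#' @return An object of class `ars_params`.
#' @export
ars_params <- function(enabled = FALSE, duration = 20L,
                       trigger = c("on_encounter", "on_capture")) {
  trigger <- match.arg(trigger)
  duration <- as.integer(duration)
  if (is.na(duration) || duration < 0L) stop("duration must be >= 0", call. = FALSE)
  structure(list(enabled = isTRUE(enabled), duration = duration,
                 trigger = trigger),
            class = "ars_params")
}

#' Capture parameters
#'
#' A predator sharing a cell with prey makes one independent Bernoulli
#' capture trial per prey item per check. When an active and an ambush
#' predator share a cell with prey, a captured prey is credited to one of
#' them by a fair draw (`contested_active_share` is the active predator's
#' win probability).
#'
#' @param capture_probability Per-encounter capture probability (0, 1].
#' @param contested_active_share Probability the active predator wins a
#'   contested capture.
#' @return An object of class `capture_params`.
#' @export
capture_params <- function(capture_probability = 1,
                           contested_active_share = 0.5) {
  if (!is.numeric(capture_probability) || capture_probability <= 0 ||
      capture_probability > 1) {
    stop("capture_probability must lie in (0, 1]", call. = FALSE)
  }
  if (contested_active_share < 0 || contested_active_share > 1) {
    stop("contested_active_share must lie in [0, 1]", call. = FALSE)
  }
  structure(list(capture_probability = as.numeric(capture_probability),
                 contested_active_share = as.numeric(contested_active_share)),
            class = "capture_params")
}

#' Prey reappearance parameters
#'
#' When enabled, each time step makes one independent Bernoulli draw per prey
#' type: on success a new mobile prey appears at a uniform random position
#' (it starts moving on the next time step), or a new sedentary prey appears
#' at a uniform position inside one of the eight Moore-neighbour cells
#' (torus-adjacent) of a uniformly chosen live sedentary prey.
#'
#' @param enabled Is reappearance active?
#' @param per_type_probability Per-time-step probability per prey type.
#' @return An object of class `reappearance_params`.
#' @export
reappearance_params <- function(enabled = FALSE, per_type_probability = 0.10) {
  if (per_type_probability < 0 || per_type_probability > 1) {
    stop("per_type_probability must lie in [0, 1]", call. = FALSE)
  }
  structure(list(enabled = isTRUE(enabled),
                 per_type_probability = as.numeric(per_type_probability)),
            class = "reappearance_params")
}
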