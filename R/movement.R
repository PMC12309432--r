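#' Draw correlated-random-walk turning angles
#'
#' Turns are uniform on `[-max_turn, +max_turn]` degrees: "turning up to X
#' degrees" per move, symmetric about straight ahead, which gives the walk
#' its directional persistence (small `max_turn`) or tortuosity (large
#' `max_turn`).
#'
#' @param n Number of draws.
#' @param max_turn Maximum turn magnitude in degrees, in `[0, 180]`.
#' @return Numeric vector of `n` signed turning angles.
#' @examples
#' set.seed(1)
#' range(sample_turn(1000, 120))
#' @export
sample_turn <- function(n, max_turn) {
  .check_turn(max_turn)
  stats::runif(n, -max_turn, max_turn)
}

# Vectorized movement core: turn, advance, handle the boundary.
# x, y, heading are parallel numeric vectors; returns the updated triple.
.advance <- function(x, y, heading, max_turn, step_length, arena) {
  h <- (heading + stats::runif(length(x), -max_turn, max_turn)) %% 360
  r <- h * (pi / 180)
  nx <- x + step_length * cos(r)
  ny <- y + step_length * sin(r)
  if (arena$boundary_mode == "wrap") {
    list(x = nx %% arena$width, y = ny %% arena$height, heading = h)
  } else {
    ref <- reflect_position(cbind(nx, ny, deparse.level = 0), h, arena)
    list(x = ref$position[, 1L], y = ref$position[, 2L], heading = ref$heading)
  }
}

#' Advance a moving agent one sub-step
#'
#' Applies one correlated-random-walk move: the heading turns by a uniform
#' draw on `[-max_turn, +max_turn]` and the agent advances `step_length`
#' cells along the new heading, with the arena's boundary handling applied.
#' Only movers (active predator, mobile prey) may be advanced; sedentary
#' prey and ambush predators are stationary by definition.
#'
#' @param agent A list with numeric `x`, `y`, `heading` (scalars or parallel
#'   vectors) and optionally `kind`.
#' @param max_turn Maximum turn in degrees.
#' @param step_length Move distance in cells.
#' @param arena An [arena_config()].
#' @return The agent with updated `x`, `y`, `heading` (normalized to
#'   `[0, 360)`).
#' @examples
#' a <- list(x = 10, y = 10, heading = 90)
#' advance_agent(a, max_turn = 0, step_length = 1, arena_config())  # (10, 11)
#' @export
advance_agent <- function(agent, max_turn, step_length = 1, arena = arena_config()) {
  if (!is.null(agent$kind) &&
      any(agent$kind %in% c("sedentary_prey", "ambush_predator"))) {
    stop("sedentary prey and ambush predators do not move", call. = FALSE)
  }
  .check_turn(max_turn)
  upd <- .advance(agent$x, agent$y, agent$heading %% 360,
                  max_turn, step_length, arena)
  agent$x <- upd$x
  agent$y <- upd$y
  agent$heading <- upd$heading
  agent
}
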