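# The per-time-step world update. Schedule, per time step:
#   1. each live mobile prey takes its unit sub-steps, with an
#      active-predator capture check after every sub-step round;
#   2. the active predator takes its unit sub-steps (max turn fixed at step
#      entry from the ARS timer), with a capture check after each;
#   3. one ambush-predator capture check (contested resolution if the two
#      predators share the cell);
#   4. ARS timer decrement;
#   5. prey reappearance, if enabled;
#   6. stop-condition check, then t <- t + 1.

# offsets of the 8 Moore-neighbour cells
.MOORE <- cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))

#' Reset the area-restricted-search timer
#'
#' Called when the active predator encounters (or, with the `"on_capture"`
#' trigger, captures) a sedentary prey: the countdown is set to the full ARS
#' duration. A trigger during a running countdown resets it — the windows do
#' not accumulate. Predators not in ARS mode are returned unchanged.
#'
#' @param predator The active-predator state (list with `mode`, `ars_timer`).
#' @param ars An [ars_params()].
#' @return The updated predator state.
#' @export
trigger_ars <- function(predator, ars) {
  if (identical(predator$mode, "ars")) predator$ars_timer <- ars$duration
  predator
}

#' Decrement the area-restricted-search timer
#'
#' Called exactly once per time step, after the predator's movement and
#' capture checks. The max turn used for the *next* step's movement reflects
#' the post-decrement timer, so a single trigger yields exactly `duration`
#' subsequent nondirectional steps.
#'
#' @param predator The active-predator state.
#' @return The updated predator state (timer floored at zero).
#' @export
tick_ars <- function(predator) {
  predator$ars_timer <- max(0L, predator$ars_timer - 1L)
  predator
}

# max turn the active predator uses this time step, from the timer as it
# stands on step entry
.active_max_turn <- function(active, movement) {
  switch(active$mode,
         fixed_directional = movement$directional_max_turn,
         fixed_nondirectional = movement$nondirectional_max_turn,
         ars = if (active$ars_timer > 0L) movement$nondirectional_max_turn
               else movement$directional_max_turn,
         stop("unknown predator mode: ", active$mode))
}

#' Resolve contested captures between the two predators
#'
#' When the active and the ambush predator occupy the same cell as prey, each
#' prey item first survives or succumbs to a single Bernoulli capture trial
#' (so the per-encounter capture probability is independent of predator
#' identity), and only a captured prey is then credited to one predator by a
#' fair draw.
#'
#' @param n Number of co-located prey items, each contested independently.
#' @param capture An optional [capture_params()] (defaults apply otherwise).
#' @return Character vector of length `n` with values `"active"`, `"ambush"`,
#'   or `"escaped"`.
#' @export
resolve_contested <- function(n, capture = capture_params()) {
  out <- rep("escaped", n)
  captured <- stats::runif(n) < capture$capture_probability
  if (any(captured)) {
    win <- stats::runif(sum(captured)) < capture$contested_active_share
    out[captured] <- ifelse(win, "active", "ambush")
  }
  out
}

#' Resolve captures in a predator's cell
#'
#' Performs one capture check: every live prey sharing the predator's cell is
#' subjected to an independent Bernoulli(`capture_probability`) trial;
#' captured prey are removed immediately and credited to the predator's
#' ledger by prey type. Multiple co-located prey are all eligible in the same
#' check; prey that survive a trial stay alive and in place. An active
#' predator check that involves a sedentary prey triggers area-restricted
#' search according to the ARS trigger rule. The ambush predator captures
#' mobile prey only, and when the active predator stands in its cell the
#' captures are contested (see [resolve_contested()]).
#'
#' @param state A `sim_state`.
#' @param predator `"active"` or `"ambush"`.
#' @return The updated `sim_state`.
#' @export
resolve_cell_captures <- function(state, predator = c("active", "ambush")) {
  predator <- match.arg(predator)
  p <- state$capture$capture_probability
  if (predator == "active") {
    act <- state$active
    pcx <- floor(act$x)
    pcy <- floor(act$y)

    mob <- state$mobile
    mi <- which(floor(mob$x) == pcx & floor(mob$y) == pcy)
    if (length(mi)) {
      caught <- if (p >= 1) mi else mi[stats::runif(length(mi)) < p]
      if (length(caught)) {
        keep <- -caught
        state$mobile <- list(x = mob$x[keep], y = mob$y[keep],
                             heading = mob$heading[keep])
        act$captured_mobile <- act$captured_mobile + length(caught)
      }
    }

    sed <- state$sedentary
    si <- which(sed$cx == pcx & sed$cy == pcy)
    n_caught_sed <- 0L
    if (length(si)) {
      caught <- if (p >= 1) si else si[stats::runif(length(si)) < p]
      n_caught_sed <- length(caught)
      if (n_caught_sed) {
        keep <- -caught
        state$sedentary <- list(x = sed$x[keep], y = sed$y[keep],
                                cx = sed$cx[keep], cy = sed$cy[keep])
        act$captured_sedentary <- act$captured_sedentary + n_caught_sed
      }
    }

    if (act$mode == "ars") {
      trig <- if (state$ars$trigger == "on_encounter") length(si) > 0L
              else n_caught_sed > 0L
      if (trig) act <- trigger_ars(act, state$ars)
    }
    state$active <- act
  } else {
    amb <- state$ambush
    if (is.null(amb)) return(state)
    mob <- state$mobile
    mi <- which(floor(mob$x) == amb$cx & floor(mob$y) == amb$cy)
    if (length(mi)) {
      contested <- floor(state$active$x) == amb$cx &&
                   floor(state$active$y) == amb$cy
      if (contested) {
        fate <- resolve_contested(length(mi), state$capture)
        caught <- mi[fate != "escaped"]
        n_active <- sum(fate == "active")
        if (n_active) {
          state$active$captured_mobile <-
            state$active$captured_mobile + n_active
        }
        amb$captured_mobile <- amb$captured_mobile + sum(fate == "ambush")
      } else {
        caught <- if (p >= 1) mi else mi[stats::runif(length(mi)) < p]
        amb$captured_mobile <- amb$captured_mobile + length(caught)
      }
      if (length(caught)) {
        keep <- -caught
        state$mobile <- list(x = mob$x[keep], y = mob$y[keep],
                             heading = mob$heading[keep])
      }
      state$ambush <- amb
    }
  }
  state
}

#' Prey reappearance
#'
#' One independent Bernoulli draw per prey type per time step. A new mobile
#' prey appears at a uniform random position with a uniform heading and
#' neither moves nor is capture-checked until the next time step. A new
#' sedentary prey appears at a uniform continuous position inside one of the
#' eight Moore-neighbour cells (chosen uniformly, torus-adjacent) of a
#' uniformly chosen live sedentary prey; with no live sedentary prey left the
#' draw is silently skipped, since no anchor exists.
#'
#' @param state A `sim_state`.
#' @return The updated `sim_state`.
#' @export
reappearance_step <- function(state) {
  rp <- state$reappearance
  if (!rp$enabled) return(state)
  pr <- rp$per_type_probability
  W <- state$arena$width
  H <- state$arena$height

  if (stats::runif(1) < pr) {
    mob <- state$mobile
    state$mobile <- list(x = c(mob$x, stats::runif(1, 0, W)),
                         y = c(mob$y, stats::runif(1, 0, H)),
                         heading = c(mob$heading, stats::runif(1, 0, 360)))
    state$reappeared["mobile"] <- state$reappeared["mobile"] + 1L
  }

  if (stats::runif(1) < pr) {
    sed <- state$sedentary
    ns <- length(sed$x)
    if (ns > 0L) {
      j <- sample.int(ns, 1L)
      k <- sample.int(8L, 1L)
      ncx <- (sed$cx[j] + .MOORE[k, 1L]) %% W
      ncy <- (sed$cy[j] + .MOORE[k, 2L]) %% H
      nx <- ncx + stats::runif(1)
      ny <- ncy + stats::runif(1)
      state$sedentary <- list(x = c(sed$x, nx), y = c(sed$y, ny),
                              cx = c(sed$cx, ncx), cy = c(sed$cy, ncy))
      state$reappeared["sedentary"] <- state$reappeared["sedentary"] + 1L
    }
  }
  state
}

#' Advance the simulation by one time step
#'
#' Executes the full event schedule: mobile-prey sub-steps with capture
#' checks, active-predator sub-steps with capture checks, the single
#' per-step ambush check, the ARS timer decrement, reappearance, and the
#' stop condition. The active predator's max turn for the whole step is
#' fixed on entry from the ARS timer, so a trigger during the step first
#' shows in the next step's movement.
#'
#' @param state A non-terminated `sim_state`.
#' @return The updated `sim_state`, with `t` incremented by exactly 1.
#' @export
simulation_step <- function(state) {
  if (state$terminated) stop("simulation already terminated", call. = FALSE)
  mv <- state$movement
  arena <- state$arena
  pred_turn <- .active_max_turn(state$active, mv)

  # (1) mobile prey move, capture checked after each sub-step round
  for (k in seq_len(mv$speed_multiplier_mobile)) {
    mob <- state$mobile
    if (length(mob$x)) {
      state$mobile <- .advance(mob$x, mob$y, mob$heading,
                               state$prey_max_turn, mv$step_length, arena)
    }
    state <- resolve_cell_captures(state, "active")
  }

  # (2) active predator moves, capture checked after each sub-step
  for (k in seq_len(mv$speed_multiplier_active)) {
    act <- state$active
    upd <- .advance(act$x, act$y, act$heading, pred_turn, mv$step_length, arena)
    act$x <- upd$x; act$y <- upd$y; act$heading <- upd$heading
    state$active <- act
    state <- resolve_cell_captures(state, "active")
  }

  # (3) ambush predator: one check per time step
  if (!is.null(state$ambush)) state <- resolve_cell_captures(state, "ambush")

  # (4) ARS timer
  state$active <- tick_ars(state$active)

  # (5) reappearance
  state <- reappearance_step(state)

  # (6) stop condition, then advance the clock
  state$t <- state$t + 1L
  total <- state$active$captured_mobile + state$active$captured_sedentary
  if (total >= state$stop_threshold) {
    state$terminated <- TRUE
    state$termination <- "threshold_reached"
  } else if (state$t >= state$max_steps) {
    state$terminated <- TRUE
    state$termination <- "max_steps"
  }
  state
}

#' Run one replicate to termination
#'
#' Initializes the world from `(scenario, seed)` and iterates
#' [simulation_step()] until the active predator's total captures reach the
#' stop threshold (default 200, i.e. half of all prey initially present) or
#' the safety cap on time steps is hit. Identical `(scenario, seed)` pairs
#' yield identical results.
#'
#' @param scenario A [scenario()].
#' @param seed Integer seed for this replicate.
#' @return An object of class `run_result`: the capture ledger by predator
#'   and prey type, reappearance counts, duration in time steps, and the
#'   termination reason.
#' @examples
#' \donttest{
#' r <- run_simulation(scenario("random"), seed = 1)
#' proportion_mobile(r)
#' }
#' @export
run_simulation <- function(scenario, seed) {
  state <- init_state(scenario, seed)
  while (!state$terminated) state <- simulation_step(state)
  structure(list(
    scenario_id = state$scenario_id,
    seed = state$seed,
    captured_mobile_active = state$active$captured_mobile,
    captured_sedentary_active = state$active$captured_sedentary,
    captured_mobile_ambush =
      if (is.null(state$ambush)) 0L else state$ambush$captured_mobile,
    reappeared_mobile = unname(state$reappeared["mobile"]),
    reappeared_sedentary = unname(state$reappeared["sedentary"]),
    alive_mobile = length(state$mobile$x),
    alive_sedentary = length(state$sedentary$x),
    duration_steps = state$t,
    termination = state$termination
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "<run_result %s seed=%d | active: %d mobile + %d sedentary | ambush: %d mobile | %d steps (%s)>\n",
    x$scenario_id, x$seed, x$captured_mobile_active,
    x$captured_sedentary_active, x$captured_mobile_ambush,
    x$duration_steps, x$termination))
  invisible(x)
}
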