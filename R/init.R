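#' Random placement of sedentary prey
#'
#' Places `n` sedentary prey independently and uniformly over the continuous
#' arena.
#'
#' @param n Number of prey.
#' @param arena An [arena_config()].
#' @return An `n` x 2 matrix of positions.
#' @export
init_sedentary_random <- function(n, arena = arena_config()) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  cbind(x = stats::runif(n, 0, arena$width),
        y = stats::runif(n, 0, arena$height))
}

#' Clumped placement of sedentary prey
#'
#' Draws `n_patches` patch centers uniformly over the arena, then places
#' `per_patch` prey uniformly over the disc of the given radius about each
#' center. Discs wrap across the torus boundary, and centers may overlap;
#' the radius constraint holds in torus distance.
#'
#' @param n_patches Number of patches.
#' @param per_patch Prey per patch.
#' @param radius Patch radius in cells (>= 0).
#' @param arena An [arena_config()].
#' @return An `(n_patches * per_patch)` x 2 position matrix with attributes
#'   `centers` (the patch centers) and `patch` (the generating patch of each
#'   row).
#' @export
init_sedentary_clumped <- function(n_patches = 8L, per_patch = 25L,
                                   radius = 5, arena = arena_config()) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  n_patches <- as.integer(n_patches)
  per_patch <- as.integer(per_patch)
  centers <- cbind(x = stats::runif(n_patches, 0, arena$width),
                   y = stats::runif(n_patches, 0, arena$height))
  n <- n_patches * per_patch
  patch <- rep(seq_len(n_patches), each = per_patch)
  # uniform over the disc: sqrt-radius trick
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  pos <- cbind(x = centers[patch, 1L] + r * cos(th),
               y = centers[patch, 2L] + r * sin(th))
  pos <- wrap_position(pos, arena)
  attr(pos, "centers") <- centers
  attr(pos, "patch") <- patch
  pos
}

#' Initialize a simulation state
#'
#' Builds the complete world for one replicate: sedentary prey placed by the
#' scenario's spatial pattern, mobile prey uniform over the arena, the active
#' predator (and optionally the ambush predator) at uniform random positions,
#' all mover headings i.i.d. uniform on `[0, 360)`, the ARS timer at zero, and
#' a zeroed capture ledger. The global RNG is seeded from `seed`, so the state
#' (and any run grown from it) is a pure function of `(scenario, seed)`.
#'
#' @param scenario A [scenario()].
#' @param seed Integer seed.
#' @return An object of class `sim_state`.
#' @export
init_state <- function(scenario, seed) {
  stopifnot(inherits(scenario, "foragesim_scenario"))
  set.seed(as.integer(seed))
  arena <- scenario$arena
  W <- arena$width
  H <- arena$height

  if (scenario$spatial_pattern == "clumped") {
    cl <- scenario$clump
    sed <- init_sedentary_clumped(cl$n_patches, cl$per_patch, cl$radius, arena)
    n_sed <- nrow(sed)
  } else {
    n_sed <- scenario$n_sedentary
    sed <- init_sedentary_random(n_sed, arena)
  }
  if (scenario$predator_mode == "ars" && n_sed == 0L) {
    stop("ARS mode requires sedentary prey to trigger on", call. = FALSE)
  }

  n_mob <- scenario$n_mobile
  mobile <- list(x = stats::runif(n_mob, 0, W),
                 y = stats::runif(n_mob, 0, H),
                 heading = stats::runif(n_mob, 0, 360))

  active <- list(x = stats::runif(1, 0, W), y = stats::runif(1, 0, H),
                 heading = stats::runif(1, 0, 360),
                 kind = "active_predator",
                 mode = scenario$predator_mode,
                 ars_timer = 0L,
                 captured_mobile = 0L, captured_sedentary = 0L)

  ambush <- NULL
  if (scenario$ambush_present) {
    bx <- stats::runif(1, 0, W)
    by <- stats::runif(1, 0, H)
    ambush <- list(x = bx, y = by, heading = 0,
                   kind = "ambush_predator",
                   cx = as.integer(floor(bx)), cy = as.integer(floor(by)),
                   captured_mobile = 0L)
  }

  structure(list(
    t = 0L,
    arena = arena,
    prey_max_turn = scenario$prey_max_turn,
    movement = scenario$movement,
    ars = scenario$ars,
    capture = scenario$capture,
    reappearance = scenario$reappearance,
    active = active,
    ambush = ambush,
    mobile = mobile,
    sedentary = list(x = sed[, 1L], y = sed[, 2L],
                     cx = as.integer(floor(sed[, 1L])),
                     cy = as.integer(floor(sed[, 2L]))),
    init_n = c(mobile = n_mob, sedentary = n_sed),
    reappeared = c(mobile = 0L, sedentary = 0L),
    stop_threshold = scenario$stop_threshold,
    max_steps = scenario$max_steps,
    terminated = FALSE,
    termination = NA_character_,
    scenario_id = scenario$id,
    seed = as.integer(seed)
  ), class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "<sim_state t=%d | mobile %d alive, sedentary %d alive | active captures %d+%d%s%s>\n",
    x$t, length(x$mobile$x), length(x$sedentary$x),
    x$active$captured_mobile, x$active$captured_sedentary,
    if (!is.null(x$ambush)) sprintf(" | ambush captures %d", x$ambush$captured_mobile) else "",
    if (x$terminated) sprintf(" | terminated (%s)", x$termination) else ""))
  invisible(x)
}
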