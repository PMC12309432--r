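#' Treatment specification
#'
#' One experimental treatment: which movement, speed, capture, and
#' reappearance knobs deviate from the defaults. `"D"` is directional
#' movement (max turn 10 degrees), `"ND"` nondirectional (120 degrees), and
#' `"ARS"` area-restricted search (directional until a sedentary prey is
#' encountered, then nondirectional for 20 steps).
#'
#' @param prey_directionality `"D"` or `"ND"` for the mobile prey.
#' @param predator_mode `"D"`, `"ND"`, or `"ARS"` for the active predator.
#' @param speed_double `"none"`, `"prey"` (mobile prey take two unit
#'   sub-steps per time step), or `"predator"` (the active predator does).
#' @param capture_probability Per-encounter capture probability (1 or 0.5 in
#'   the catalog; any value in (0, 1] accepted).
#' @param reappearance Enable the 10% per-step prey reappearance process?
#' @return An object of class `foragesim_treatment`.
#' @export
treatment <- function(prey_directionality = c("D", "ND"),
                      predator_mode = c("D", "ARS", "ND"),
                      speed_double = c("none", "prey", "predator"),
                      capture_probability = 1,
                      reappearance = FALSE) {
  structure(list(
    prey_directionality = match.arg(prey_directionality),
    predator_mode = match.arg(predator_mode),
    speed_double = match.arg(speed_double),
    capture_probability = capture_probability,
    reappearance = isTRUE(reappearance)
  ), class = "foragesim_treatment")
}

.mode_map <- c(D = "fixed_directional", ND = "fixed_nondirectional", ARS = "ars")

# human-readable treatment slug, relative to the pattern's default predator
# (directional in the random pattern, ARS in the clumped pattern)
.treatment_slug <- function(tr, spatial_pattern) {
  default_pred <- if (spatial_pattern == "clumped") "ARS" else "D"
  parts <- character(0)
  if (tr$prey_directionality == "ND") parts <- c(parts, "prey-nd")
  if (tr$predator_mode != default_pred) {
    parts <- c(parts, paste0("pred-", tolower(tr$predator_mode)))
  }
  if (tr$speed_double == "prey") parts <- c(parts, "prey-speed-x2")
  if (tr$speed_double == "predator") parts <- c(parts, "pred-speed-x2")
  if (tr$capture_probability < 1) {
    parts <- c(parts, sprintf("capture-%g", 100 * tr$capture_probability))
  }
  if (tr$reappearance) parts <- c(parts, "reappear")
  if (!length(parts)) "default" else paste(parts, collapse = "+")
}

#' Scenario specification
#'
#' The complete, immutable description of one experimental condition: the
#' spatial pattern of sedentary prey, whether an ambush predator is present,
#' the treatment, and every engine parameter. All defaults are the study
#' conditions: a 51 x 51 wrapped arena, 200 mobile and 200 sedentary prey, a
#' stop threshold of 200 active-predator captures, 20-step ARS triggered by
#' encounter, 10% reappearance probability when enabled.
#'
#' @param spatial_pattern `"random"` (sedentary prey uniform over the arena)
#'   or `"clumped"` (8 patches of 25 prey within a 5-cell radius).
#' @param ambush_present Add one stationary ambush predator?
#' @param treatment A [treatment()]. By default the pattern's default
#'   treatment (directional prey; directional predator in the random
#'   pattern, ARS predator in the clumped pattern).
#' @param arena An [arena_config()].
#' @param n_mobile,n_sedentary Initial prey counts (random pattern; the
#'   clumped pattern's sedentary count is `n_patches * per_patch`).
#' @param clump Clumped-pattern geometry: list with `n_patches`, `per_patch`,
#'   `radius`.
#' @param ars_duration ARS countdown length in time steps.
#' @param ars_trigger `"on_encounter"` or `"on_capture"`.
#' @param reappearance_probability Per-type per-step reappearance
#'   probability (used when the treatment enables reappearance).
#' @param directional_max_turn,nondirectional_max_turn Turn limits, degrees.
#' @param stop_threshold Active-predator captures that end a run (inclusive).
#' @param max_steps Safety cap on time steps.
#' @param id Scenario identifier; derived from the fields if `NULL`.
#' @return An object of class `foragesim_scenario`.
#' @examples
#' scenario("random")
#' scenario("clumped", ambush_present = TRUE,
#'          treatment = treatment("D", "ARS", capture_probability = 0.5))
#' @export
scenario <- function(spatial_pattern = c("random", "clumped"),
                     ambush_present = FALSE,
                     treatment = NULL,
                     arena = arena_config(),
                     n_mobile = 200L,
                     n_sedentary = 200L,
                     clump = list(n_patches = 8L, per_patch = 25L, radius = 5),
                     ars_duration = 20L,
                     ars_trigger = c("on_encounter", "on_capture"),
                     reappearance_probability = 0.10,
                     directional_max_turn = 10,
                     nondirectional_max_turn = 120,
                     stop_threshold = 200L,
                     max_steps = 1e6,
                     id = NULL) {
  spatial_pattern <- match.arg(spatial_pattern)
  ars_trigger <- match.arg(ars_trigger)
  if (is.null(treatment)) {
    treatment <- treatment(
      predator_mode = if (spatial_pattern == "clumped") "ARS" else "D")
  }
  stopifnot(inherits(treatment, "foragesim_treatment"),
            inherits(arena, "arena_config"))
  if (stop_threshold < 1L) stop("stop_threshold must be >= 1", call. = FALSE)

  movement <- movement_params(
    directional_max_turn = directional_max_turn,
    nondirectional_max_turn = nondirectional_max_turn,
    step_length = 1,
    speed_multiplier_active = if (treatment$speed_double == "predator") 2L else 1L,
    speed_multiplier_mobile = if (treatment$speed_double == "prey") 2L else 1L)
  prey_max_turn <- if (treatment$prey_directionality == "ND") {
    movement$nondirectional_max_turn
  } else {
    movement$directional_max_turn
  }
  predator_mode <- .mode_map[[treatment$predator_mode]]

  if (is.null(id)) {
    id <- paste(spatial_pattern,
                if (ambush_present) "ambush" else "solo",
                .treatment_slug(treatment, spatial_pattern), sep = "/")
  }

  structure(list(
    id = id,
    spatial_pattern = spatial_pattern,
    ambush_present = isTRUE(ambush_present),
    treatment = treatment,
    arena = arena,
    movement = movement,
    prey_max_turn = prey_max_turn,
    predator_mode = predator_mode,
    ars = ars_params(enabled = predator_mode == "ars",
                     duration = ars_duration, trigger = ars_trigger),
    capture = capture_params(treatment$capture_probability),
    reappearance = reappearance_params(
      enabled = treatment$reappearance,
      per_type_probability = reappearance_probability),
    n_mobile = as.integer(n_mobile),
    n_sedentary = as.integer(n_sedentary),
    clump = clump,
    stop_threshold = as.integer(stop_threshold),
    max_steps = as.integer(max_steps)
  ), class = "foragesim_scenario")
}

#' @export
print.foragesim_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s>\n", x$id))
  invisible(x)
}

# the 18 treatment rows of the catalog, in table order (9 per spatial pattern)
.catalog_rows <- function() {
  list(
    list(pattern = "random",  tr = treatment("D", "D")),
    list(pattern = "random",  tr = treatment("D", "ARS")),
    list(pattern = "random",  tr = treatment("ND", "D")),
    list(pattern = "random",  tr = treatment("D", "ND")),
    list(pattern = "random",  tr = treatment("ND", "ND")),
    list(pattern = "random",  tr = treatment("D", "D", "prey")),
    list(pattern = "random",  tr = treatment("D", "D", "predator")),
    list(pattern = "random",  tr = treatment("D", "D", capture_probability = 0.5)),
    list(pattern = "random",  tr = treatment("D", "D", reappearance = TRUE)),
    list(pattern = "clumped", tr = treatment("D", "D")),
    list(pattern = "clumped", tr = treatment("D", "ARS")),
    list(pattern = "clumped", tr = treatment("ND", "ARS")),
    list(pattern = "clumped", tr = treatment("D", "ND")),
    list(pattern = "clumped", tr = treatment("ND", "ND")),
    list(pattern = "clumped", tr = treatment("D", "ARS", "prey")),
    list(pattern = "clumped", tr = treatment("D", "ARS", "predator")),
    list(pattern = "clumped", tr = treatment("D", "ARS", capture_probability = 0.5)),
    list(pattern = "clumped", tr = treatment("D", "ARS", reappearance = TRUE))
  )
}

#' Build the full scenario catalog
#'
#' Expands the 18 treatment rows (9 per spatial pattern of sedentary prey)
#' with the ambush predator absent and present, giving the 36 experimental
#' conditions. Identifiers are stable slugs of the form
#' `pattern/solo-or-ambush/treatment`, e.g. `"clumped/ambush/pred-speed-x2"`.
#'
#' @param ... Engine overrides passed to every [scenario()] (e.g.
#'   `stop_threshold`, `arena`).
#' @return A named list of 36 `foragesim_scenario` objects, in catalog order
#'   (each row expanded ambush-absent then ambush-present).
#' @examples
#' names(build_scenario_table())[1:4]
#' @export
build_scenario_table <- function(...) {
  rows <- .catalog_rows()
  out <- list()
  for (row in rows) {
    for (amb in c(FALSE, TRUE)) {
      sc <- scenario(row$pattern, ambush_present = amb, treatment = row$tr, ...)
      out[[sc$id]] <- sc
    }
  }
  out
}

#' Summarize the scenario catalog as a data frame
#'
#' @param scenarios A list of scenarios, by default the full catalog.
#' @return A data frame with one row per scenario: id, spatial pattern,
#'   ambush flag, and the treatment fields.
#' @export
list_scenarios <- function(scenarios = build_scenario_table()) {
  do.call(rbind, lapply(scenarios, function(sc) {
    tr <- sc$treatment
    data.frame(id = sc$id,
               spatial_pattern = sc$spatial_pattern,
               ambush = sc$ambush_present,
               prey_directionality = tr$prey_directionality,
               predator_mode = tr$predator_mode,
               speed_double = tr$speed_double,
               capture_probability = tr$capture_probability,
               reappearance = tr$reappearance,
               row.names = NULL)
  }))
}

#' Run a replicated experiment
#'
#' Runs `n_reps` independent replicates of one scenario, replicate `r` using
#' seed `base_seed + r - 1`, so a whole experiment is reproducible from
#' `(scenario, base_seed)` and results do not depend on execution order.
#'
#' @param scenario A [scenario()].
#' @param n_reps Number of replicates (the study design uses 50).
#' @param base_seed Seed of the first replicate.
#' @return A data frame of run records, one row per replicate, with the
#'   columns `scenario_id`, `replicate`, `seed`, `captured_mobile_active`,
#'   `captured_sedentary_active`, `captured_mobile_ambush`,
#'   `reappeared_mobile`, `reappeared_sedentary`, `duration_steps`,
#'   `termination`, `proportion_mobile`.
#' @examples
#' \donttest{
#' runs <- run_experiment(scenario("random"), n_reps = 3, base_seed = 1)
#' mean(runs$proportion_mobile)
#' }
#' @export
run_experiment <- function(scenario, n_reps = 50L, base_seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  seeds <- as.integer(base_seed) + seq_len(n_reps) - 1L
  results <- lapply(seeds, function(s) run_simulation(scenario, s))
  runs_to_records(results)
}

#' Convert run results to the tabular run-record form
#'
#' @param results A list of `run_result` objects (or a single one).
#' @return A run-record data frame (see [run_experiment()]).
#' @export
runs_to_records <- function(results) {
  if (inherits(results, "run_result")) results <- list(results)
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    tot <- r$captured_mobile_active + r$captured_sedentary_active
    data.frame(
      scenario_id = r$scenario_id,
      replicate = i,
      seed = r$seed,
      captured_mobile_active = r$captured_mobile_active,
      captured_sedentary_active = r$captured_sedentary_active,
      captured_mobile_ambush = r$captured_mobile_ambush,
      reappeared_mobile = r$reappeared_mobile,
      reappeared_sedentary = r$reappeared_sedentary,
      duration_steps = r$duration_steps,
      termination = r$termination,
      proportion_mobile =
        if (tot > 0L) round(r$captured_mobile_active / tot, 6) else NA_real_,
      row.names = NULL)
  }))
}
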