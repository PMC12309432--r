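.RUN_COLS <- c("scenario_id", "replicate", "seed",
               "captured_mobile_active", "captured_sedentary_active",
               "captured_mobile_ambush", "reappeared_mobile",
               "reappeared_sedentary", "duration_steps", "termination",
               "proportion_mobile")

#' Write and read run records
#'
#' Plain CSV with a fixed column set and no quoting, so a
#' write-read-write cycle is byte-stable.
#'
#' @param runs A run-record data frame (see [run_experiment()]).
#' @param path Output file.
#' @return `write_runs` returns `path` invisibly; `read_runs` returns the
#'   run-record data frame.
#' @export
write_runs <- function(runs, path) {
  stopifnot(is.data.frame(runs), all(.RUN_COLS %in% names(runs)))
  utils::write.csv(runs[.RUN_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_runs
#' @export
read_runs <- function(path) {
  utils::read.csv(path, colClasses = c(
    scenario_id = "character", replicate = "integer", seed = "integer",
    captured_mobile_active = "integer", captured_sedentary_active = "integer",
    captured_mobile_ambush = "integer", reappeared_mobile = "integer",
    reappeared_sedentary = "integer", duration_steps = "integer",
    termination = "character", proportion_mobile = "numeric"))
}

#' Write and read scenario summaries
#'
#' @param summary A summary data frame (see [summarize_runs()]).
#' @param path Output file.
#' @return `write_summary` returns `path` invisibly; `read_summary` the
#'   summary data frame.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  utils::read.csv(path, colClasses = c(
    scenario_id = "character", n = "integer", mean = "numeric",
    ci_low = "numeric", ci_high = "numeric"))
}

# allowed configuration schema: NA = scalar leaf, otherwise nested key set
.CONFIG_SCHEMA <- list(
  spatial_pattern = NA, ambush_present = NA,
  n_mobile = NA, n_sedentary = NA,
  stop_threshold = NA, max_steps = NA,
  ars_duration = NA, ars_trigger = NA,
  reappearance_probability = NA,
  directional_max_turn = NA, nondirectional_max_turn = NA,
  treatment = list(prey_directionality = NA, predator_mode = NA,
                   speed_double = NA, capture_probability = NA,
                   reappearance = NA),
  arena = list(width = NA, height = NA, boundary_mode = NA),
  clump = list(n_patches = NA, per_patch = NA, radius = NA)
)

.validate_config <- function(cfg, schema = .CONFIG_SCHEMA, prefix = "") {
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  for (key in names(cfg)) {
    path <- paste0(prefix, key)
    if (!key %in% names(schema)) {
      stop("unknown config key: ", path, call. = FALSE)
    }
    if (is.list(schema[[key]])) {
      .validate_config(cfg[[key]], schema[[key]], paste0(path, "."))
    }
  }
  cfg
}

#' Load scenario overrides from a config file
#'
#' Reads a YAML or JSON mapping of scenario fields (see [scenario()] for the
#' keys: `spatial_pattern`, `ambush_present`, nested `treatment`, `arena`,
#' and `clump` blocks, `stop_threshold`, `ars_duration`, `ars_trigger`,
#' `reappearance_probability`, turn limits, prey counts, `max_steps`).
#' Unknown keys are rejected with their dotted path; absent keys fall back
#' to the study defaults. Every sensitivity-analysis knob (boundary mode,
#' arena size, stop threshold, turn limits, reappearance probability) is
#' reachable this way.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A validated named list of overrides (class `scenario_overrides`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
  if (is.null(cfg)) cfg <- list()
  structure(.validate_config(cfg), class = "scenario_overrides")
}

#' Build a scenario from overrides
#'
#' Applies config overrides on top of the study defaults. The `arena` block
#' becomes an [arena_config()], the `treatment` block a [treatment()]; all
#' other keys map one-to-one onto [scenario()] arguments.
#'
#' @param overrides A list as returned by [load_config()] (or any subset of
#'   its keys), possibly empty.
#' @return A `foragesim_scenario`.
#' @examples
#' scenario_from_config(list(stop_threshold = 100, arena = list(width = 41, height = 41)))
#' @export
scenario_from_config <- function(overrides = list()) {
  overrides <- .validate_config(unclass(overrides))
  args <- overrides
  if (!is.null(args$arena)) args$arena <- do.call(arena_config, args$arena)
  if (!is.null(args$treatment)) args$treatment <- do.call(treatment, args$treatment)
  if (!is.null(args$clump)) {
    cl <- list(n_patches = 8L, per_patch = 25L, radius = 5)
    cl[names(args$clump)] <- args$clump
    args$clump <- cl
  }
  do.call(scenario, args)
}

# engine-level overrides applicable across a whole catalog (everything but
# the pattern/ambush/treatment identity of each scenario)
.ENGINE_KEYS <- c("n_mobile", "n_sedentary", "stop_threshold", "max_steps",
                  "ars_duration", "ars_trigger", "reappearance_probability",
                  "directional_max_turn", "nondirectional_max_turn",
                  "arena", "clump")

.log_run <- function(quiet, fmt, ...) {
  if (!quiet) {
    message(sprintf("[foragesim %s] ",
                    as.character(utils::packageVersion("foragesim"))),
            sprintf(fmt, ...))
  }
}

#' Plot per-scenario proportions for one spatial pattern
#'
#' Point-and-interval plot of the mean proportion of mobile prey captured
#' with its 95% bootstrap interval, one panel without and one with the
#' ambush predator, and a dashed reference line at 0.5 (no preference for
#' either prey type).
#'
#' @param summary A summary data frame (see [summarize_runs()]), e.g. read
#'   back from `summary.csv`.
#' @param spatial_pattern `"random"` or `"clumped"`: which half of the
#'   catalog to show.
#' @return A ggplot object.
#' @export
plot_proportions <- function(summary, spatial_pattern = c("random", "clumped")) {
  spatial_pattern <- match.arg(spatial_pattern)
  parts <- strsplit(summary$scenario_id, "/", fixed = TRUE)
  summary$pattern <- vapply(parts, `[`, "", 1L)
  summary$panel <- ifelse(vapply(parts, `[`, "", 2L) == "ambush",
                          "active + ambush predator", "active predator only")
  summary$treatment <- vapply(parts, `[`, "", 3L)
  d <- summary[summary$pattern == spatial_pattern, , drop = FALSE]
  d$treatment <- factor(d$treatment, levels = unique(d$treatment))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "blue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Proportion of mobile prey captured",
                  title = sprintf("%s spatial pattern of sedentary prey",
                                  tools::toTitleCase(spatial_pattern))) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Reproduce the full experiment catalog
#'
#' Runs every scenario in the catalog for `reps` replicates, writes
#' `runs.csv` and `summary.csv` to `out_dir`, and regenerates the two
#' two-panel figures (random and clumped pattern, each without/with the
#' ambush predator) from the summary file on disk — never from in-memory
#' state, so the plotting layer stays decoupled. Replicate seeds are
#' `base_seed + (i - 1) * reps + (r - 1)` for scenario `i`, replicate `r`.
#' Replicates that hit the time-step cap are excluded from summaries with a
#' warning.
#'
#' @param out_dir Output directory (created if needed).
#' @param base_seed Base seed for the whole catalog.
#' @param reps Replicates per scenario (the study design uses 50).
#' @param n_boot Bootstrap resamples per scenario.
#' @param overrides Optional engine-level overrides (list or
#'   [load_config()] output) applied to every scenario: arena, stop
#'   threshold, turn limits, prey counts, ARS and reappearance settings.
#' @param quiet Suppress per-scenario log messages?
#' @return The summary data frame, invisibly.
#' @export
reproduce_paper <- function(out_dir, base_seed = 1L, reps = 50L,
                            n_boot = 10000L, overrides = NULL,
                            quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- list()
  if (!is.null(overrides)) {
    overrides <- .validate_config(unclass(overrides))
    bad <- setdiff(names(overrides), .ENGINE_KEYS)
    if (length(bad)) {
      stop("only engine-level overrides apply to the catalog; not: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    args <- overrides
    if (!is.null(args$arena)) args$arena <- do.call(arena_config, args$arena)
  }
  scens <- do.call(build_scenario_table, args)

  all_runs <- vector("list", length(scens))
  for (i in seq_along(scens)) {
    sc <- scens[[i]]
    seed_i <- as.integer(base_seed + (i - 1L) * reps)
    .log_run(quiet, "scenario %s | base seed %d | %d reps", sc$id, seed_i, reps)
    all_runs[[i]] <- run_experiment(sc, n_reps = reps, base_seed = seed_i)
  }
  runs <- do.call(rbind, all_runs)
  write_runs(runs, file.path(out_dir, "runs.csv"))

  summary <- summarize_runs(read_runs(file.path(out_dir, "runs.csv")),
                            n_boot = n_boot, seed = base_seed)
  write_summary(summary, file.path(out_dir, "summary.csv"))

  plotted <- read_summary(file.path(out_dir, "summary.csv"))
  for (pat in c("random", "clumped")) {
    fig <- plot_proportions(plotted, pat)
    ggplot2::ggsave(file.path(out_dir, sprintf("fig-%s.png", pat)), fig,
                    width = 8, height = 7, dpi = 150)
  }
  invisible(summary)
}
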