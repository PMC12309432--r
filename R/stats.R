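#' Proportion of mobile prey captured
#'
#' The study's headline statistic: the active predator's mobile captures
#' divided by its total captures. Values above 0.5 indicate the predator
#' captured mobile prey more often than sedentary prey. Only the active
#' predator's ledger enters; ambush captures are ignored.
#'
#' @param result A `run_result`, a run-record data frame row set, or a
#'   numeric `c(mobile, sedentary)` pair of capture counts.
#' @return Numeric proportion(s) in `[0, 1]`.
#' @examples
#' proportion_mobile(c(150, 50))  # 0.75
#' @export
proportion_mobile <- function(result) {
  if (inherits(result, "run_result")) {
    m <- result$captured_mobile_active
    s <- result$captured_sedentary_active
  } else if (is.data.frame(result)) {
    m <- result$captured_mobile_active
    s <- result$captured_sedentary_active
  } else if (is.numeric(result) && length(result) == 2L) {
    m <- result[[1L]]
    s <- result[[2L]]
  } else {
    stop("cannot extract capture counts from this object", call. = FALSE)
  }
  tot <- m + s
  if (any(tot == 0)) {
    stop("proportion undefined: the active predator captured no prey",
         call. = FALSE)
  }
  unname(m / tot)
}

#' Percentile bootstrap confidence interval for a mean proportion
#'
#' Draws `n_boot` resamples of the replicate proportions with replacement
#' (each the size of the original sample), computes each resample's mean,
#' sorts the `n_boot` means, and reads the interval off the order statistics
#' at ranks `ceiling(alpha/2 * n_boot)` and `ceiling((1 - alpha/2) * n_boot)`
#' — ranks 250 and 9,750 at the defaults of 10,000 resamples and a 95%
#' interval.
#'
#' @param values Numeric vector of per-replicate proportions (non-empty).
#' @param n_boot Number of bootstrap resamples.
#' @param alpha Two-sided error rate (0.05 for a 95% interval).
#' @param seed Optional seed for the bootstrap resampling; when given, the
#'   global RNG state is saved and restored so evaluation never perturbs
#'   simulation streams.
#' @return Named numeric vector `c(mean, ci_low, ci_high)`, where `mean` is
#'   the plain sample mean of `values`.
#' @examples
#' set.seed(1)
#' bootstrap_ci(rbinom(50, 200, 0.6) / 200, n_boot = 1000)
#' @export
bootstrap_ci <- function(values, n_boot = 10000L, alpha = 0.05, seed = NULL) {
  values <- as.numeric(values)
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  n_boot <- as.integer(n_boot)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }

  n <- length(values)
  means <- rowMeans(matrix(sample(values, n * n_boot, replace = TRUE),
                           nrow = n_boot, ncol = n))
  s <- sort(means)
  lo <- s[max(1L, ceiling(alpha / 2 * n_boot))]
  hi <- s[min(n_boot, ceiling((1 - alpha / 2) * n_boot))]
  c(mean = mean(values), ci_low = lo, ci_high = hi)
}

#' Do two confidence intervals overlap?
#'
#' Treatments are called different when their 95% intervals do not overlap.
#' Intervals are closed: touching endpoints count as overlapping.
#'
#' @param a,b Either the output of [bootstrap_ci()] (anything with named
#'   `ci_low`/`ci_high` elements, including one-row summary data frames) or
#'   a numeric interval `c(low, high)`.
#' @return `TRUE` if the intervals intersect.
#' @examples
#' cis_overlap(c(0.40, 0.50), c(0.52, 0.60))  # FALSE: distinct
#' cis_overlap(c(0.40, 0.50), c(0.50, 0.60))  # TRUE: shared endpoint
#' @export
cis_overlap <- function(a, b) {
  iv <- function(z) {
    if (is.data.frame(z)) z <- as.list(z)
    nm <- names(z)
    if (!is.null(nm) && all(c("ci_low", "ci_high") %in% nm)) {
      c(as.numeric(z[["ci_low"]]), as.numeric(z[["ci_high"]]))
    } else {
      sort(as.numeric(z)[1:2])
    }
  }
  a <- iv(a)
  b <- iv(b)
  a[1L] <= b[2L] && b[1L] <= a[2L]
}

#' Summarize replicated runs per scenario
#'
#' Groups run records by scenario, drops any replicate that hit the
#' time-step safety cap (with a loud warning; such runs have no completed
#' foraging bout and would bias the proportion), and computes the mean
#' proportion of mobile prey captured with its percentile bootstrap interval.
#'
#' @param runs A run-record data frame (see [run_experiment()]).
#' @param n_boot Bootstrap resamples per scenario.
#' @param alpha Two-sided error rate.
#' @param seed Optional base seed for the bootstrap; scenario `i` (in the
#'   order of appearance) uses `seed + i - 1`.
#' @return A data frame with columns `scenario_id`, `n`, `mean`, `ci_low`,
#'   `ci_high` (interval bounds rounded to 6 decimals for stable CSV
#'   round-trips).
#' @export
summarize_runs <- function(runs, n_boot = 10000L, alpha = 0.05, seed = NULL) {
  stopifnot(is.data.frame(runs))
  capped <- runs$termination == "max_steps"
  if (any(capped)) {
    warning(sum(capped), " run(s) hit the max_steps cap and are excluded ",
            "from proportion summaries", call. = FALSE)
    runs <- runs[!capped, , drop = FALSE]
  }
  ids <- unique(runs$scenario_id)
  out <- lapply(seq_along(ids), function(i) {
    vals <- runs$proportion_mobile[runs$scenario_id == ids[[i]]]
    ci <- bootstrap_ci(vals, n_boot = n_boot, alpha = alpha,
                       seed = if (is.null(seed)) NULL else seed + i - 1L)
    data.frame(scenario_id = ids[[i]],
               n = length(vals),
               mean = round(unname(ci["mean"]), 6),
               ci_low = round(unname(ci["ci_low"]), 6),
               ci_high = round(unname(ci["ci_high"]), 6),
               row.names = NULL)
  })
  do.call(rbind, out)
}
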