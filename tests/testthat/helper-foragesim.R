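# shared fixtures built in code

# a cheap scenario for engine tests: few captures needed, so runs finish fast
fast_scenario <- function(...) {
  scenario("random", stop_threshold = 30L, ...)
}

# a state with hand-placed agents: start from a seeded default state and
# overwrite the populations, so all invariants of the container hold
placed_state <- function(active_xy = c(10.5, 10.5),
                         mobile_xy = NULL, sedentary_xy = NULL,
                         ambush_xy = NULL, capture_probability = 1,
                         predator_mode = "D", seed = 42, ...) {
  sc <- scenario("random",
                 ambush_present = !is.null(ambush_xy),
                 treatment = treatment("D", predator_mode,
                                       capture_probability = capture_probability),
                 ...)
  st <- init_state(sc, seed)
  st$active$x <- active_xy[1]
  st$active$y <- active_xy[2]
  if (is.null(mobile_xy)) mobile_xy <- matrix(numeric(0), ncol = 2)
  if (is.null(sedentary_xy)) sedentary_xy <- matrix(numeric(0), ncol = 2)
  st$mobile <- list(x = mobile_xy[, 1], y = mobile_xy[, 2],
                    heading = rep(0, nrow(mobile_xy)))
  st$sedentary <- list(x = sedentary_xy[, 1], y = sedentary_xy[, 2],
                       cx = as.integer(floor(sedentary_xy[, 1])),
                       cy = as.integer(floor(sedentary_xy[, 2])))
  st$init_n <- c(mobile = nrow(mobile_xy), sedentary = nrow(sedentary_xy))
  if (!is.null(ambush_xy)) {
    st$ambush$x <- ambush_xy[1]
    st$ambush$y <- ambush_xy[2]
    st$ambush$cx <- as.integer(floor(ambush_xy[1]))
    st$ambush$cy <- as.integer(floor(ambush_xy[2]))
  }
  st
}

# conservation ledger identity, per prey type
expect_conserved <- function(state) {
  amb_m <- if (is.null(state$ambush)) 0L else state$ambush$captured_mobile
  expect_identical(
    unname(state$init_n["mobile"] + state$reappeared["mobile"]),
    length(state$mobile$x) + state$active$captured_mobile + amb_m)
  expect_identical(
    unname(state$init_n["sedentary"] + state$reappeared["sedentary"]),
    length(state$sedentary$x) + state$active$captured_sedentary)
}

# signed heading difference in (-180, 180]
heading_diff <- function(h2, h1) {
  d <- (h2 - h1) %% 360
  ifelse(d > 180, d - 360, d)
}
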