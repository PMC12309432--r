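test_that("co-located prey are captured with certainty at probability 1", {
  st <- placed_state(active_xy = c(10.5, 10.5),
                     mobile_xy = rbind(c(10.2, 10.7)))
  out <- resolve_cell_captures(st, "active")
  expect_identical(out$active$captured_mobile, 1L)
  expect_equal(length(out$mobile$x), 0)

  # one mobile and one sedentary in the same cell: both captured in one check
  st2 <- placed_state(active_xy = c(10.5, 10.5),
                      mobile_xy = rbind(c(10.2, 10.7)),
                      sedentary_xy = rbind(c(10.8, 10.1)))
  out2 <- resolve_cell_captures(st2, "active")
  expect_identical(out2$active$captured_mobile, 1L)
  expect_identical(out2$active$captured_sedentary, 1L)
  expect_conserved(out2)

  # prey one cell over is untouched
  st3 <- placed_state(active_xy = c(10.5, 10.5),
                      mobile_xy = rbind(c(11.2, 10.7)))
  out3 <- resolve_cell_captures(st3, "active")
  expect_identical(out3$active$captured_mobile, 0L)
  expect_equal(length(out3$mobile$x), 1)
})

test_that("uncertain capture succeeds at the configured frequency", {
  st <- placed_state(active_xy = c(10.5, 10.5),
                     mobile_xy = rbind(c(10.4, 10.6)),
                     capture_probability = 0.5)
  set.seed(31)
  hits <- sum(vapply(1:10000, function(i) {
    resolve_cell_captures(st, "active")$active$captured_mobile
  }, integer(1)))
  expect_lt(abs(hits / 10000 - 0.5), 0.02)
})

test_that("contested captures split evenly and respect capture probability", {
  set.seed(32)
  fate <- resolve_contested(10000, capture_params(1))
  expect_true(all(fate %in% c("active", "ambush")))
  expect_lt(abs(mean(fate == "active") - 0.5), 0.02)

  fate50 <- resolve_contested(10000, capture_params(0.5))
  expect_lt(abs(mean(fate50 == "escaped") - 0.5), 0.02)
  caught <- fate50[fate50 != "escaped"]
  expect_lt(abs(mean(caught == "active") - 0.5), 0.05)
})

test_that("the ambush predator captures mobile prey only, once per step", {
  st <- placed_state(active_xy = c(40.5, 40.5),
                     mobile_xy = rbind(c(5.2, 5.7)),
                     sedentary_xy = rbind(c(5.6, 5.3)),
                     ambush_xy = c(5.5, 5.5))
  out <- resolve_cell_captures(st, "ambush")
  expect_identical(out$ambush$captured_mobile, 1L)
  expect_equal(length(out$sedentary$x), 1)   # sedentary prey ignored
  expect_identical(out$active$captured_mobile, 0L)
  expect_conserved(out)
})

test_that("a lone predator in the cell captures uncontested", {
  st <- placed_state(active_xy = c(5.5, 5.5),
                     mobile_xy = rbind(c(5.2, 5.7)),
                     ambush_xy = c(40.5, 40.5))
  out <- resolve_cell_captures(st, "active")
  expect_identical(out$active$captured_mobile, 1L)
  expect_identical(out$ambush$captured_mobile, 0L)
})

test_that("both predators in one cell contest each prey independently", {
  st <- placed_state(active_xy = c(5.5, 5.5),
                     mobile_xy = rbind(c(5.2, 5.7)),
                     ambush_xy = c(5.4, 5.6))
  set.seed(33)
  wins <- vapply(1:4000, function(i) {
    out <- resolve_cell_captures(st, "ambush")
    c(out$active$captured_mobile, out$ambush$captured_mobile)
  }, integer(2))
  expect_equal(unique(colSums(wins)), 1)  # exactly one predator credited
  expect_lt(abs(mean(wins[1, ]) - 0.5), 0.025)
})

test_that("ARS triggers reset the timer in full, never additively", {
  ars <- ars_params(enabled = TRUE, duration = 20)
  pred <- list(mode = "ars", ars_timer = 0L)
  expect_identical(trigger_ars(pred, ars)$ars_timer, 20L)
  pred$ars_timer <- 7L
  expect_identical(trigger_ars(pred, ars)$ars_timer, 20L)
  fixed <- list(mode = "fixed_directional", ars_timer = 0L)
  expect_identical(trigger_ars(fixed, ars), fixed)
  expect_identical(tick_ars(list(mode = "ars", ars_timer = 0L))$ars_timer, 0L)
  expect_identical(tick_ars(list(mode = "ars", ars_timer = 20L))$ars_timer, 19L)
})

test_that("an encounter with sedentary prey switches the predator to ARS", {
  st <- placed_state(active_xy = c(10.5, 10.5),
                     sedentary_xy = rbind(c(10.2, 10.7)),
                     predator_mode = "ARS")
  out <- resolve_cell_captures(st, "active")
  expect_identical(out$active$ars_timer, 20L)
  # mobile-prey encounters never trigger ARS
  st2 <- placed_state(active_xy = c(10.5, 10.5),
                      mobile_xy = rbind(c(10.2, 10.7)),
                      predator_mode = "ARS")
  expect_identical(resolve_cell_captures(st2, "active")$active$ars_timer, 0L)
})

test_that("on_capture trigger fires only on successful captures", {
  sc <- scenario("random",
                 treatment = treatment("D", "ARS", capture_probability = 0.5),
                 ars_trigger = "on_capture")
  st <- init_state(sc, 7)
  st$mobile <- list(x = numeric(0), y = numeric(0), heading = numeric(0))
  st$init_n["mobile"] <- 0L
  st$active$x <- 10.5; st$active$y <- 10.5
  st$sedentary <- list(x = 10.4, y = 10.6, cx = 10L, cy = 10L)
  st$init_n["sedentary"] <- 1L
  set.seed(34)
  out <- replicate(2000, {
    r <- resolve_cell_captures(st, "active")
    c(r$active$captured_sedentary, r$active$ars_timer)
  })
  # the timer is set exactly when the capture succeeded
  expect_identical(unname(out[2, ] == 20L), unname(out[1, ] == 1L))
  expect_lt(abs(mean(out[1, ]) - 0.5), 0.03)
})

test_that("ARS turning envelope: 120-degree turns iff the timer is running", {
  sc <- scenario("clumped", treatment = treatment("D", "ARS"),
                 stop_threshold = 1000L)
  st <- init_state(sc, 55)
  # empty the arena so nothing interferes with the predator's walk
  st$mobile <- list(x = numeric(0), y = numeric(0), heading = numeric(0))
  st$sedentary <- list(x = numeric(0), y = numeric(0),
                       cx = integer(0), cy = integer(0))
  st$init_n <- c(mobile = 0L, sedentary = 0L)
  st$active$ars_timer <- 8L
  set.seed(56)
  timer_in <- integer(60)
  dh <- numeric(60)
  for (i in 1:60) {
    timer_in[i] <- st$active$ars_timer
    h0 <- st$active$heading
    st <- simulation_step(st)
    dh[i] <- abs(heading_diff(st$active$heading, h0))
  }
  expect_true(all(dh[timer_in > 0] <= 120))
  expect_true(all(dh[timer_in == 0] <= 10))
  # the nondirectional phase actually uses the wide envelope
  expect_gt(max(dh[timer_in > 0]), 10)
  # timer decays by one per step and floors at zero
  expect_identical(timer_in[1:9], c(8:0))
})

test_that("a trigger during the window restarts the full countdown", {
  ars <- ars_params(TRUE, 20)
  pred <- list(mode = "ars", ars_timer = 0L)
  pred <- trigger_ars(pred, ars)            # step t
  for (i in 1:5) pred <- tick_ars(pred)     # t .. t+4
  expect_identical(pred$ars_timer, 15L)
  pred <- trigger_ars(pred, ars)            # re-encounter at t+5
  steps <- 0L
  while (pred$ars_timer > 0L) { pred <- tick_ars(pred); steps <- steps + 1L }
  expect_identical(steps, 20L)              # nondirectional through t+25
})

test_that("reappearance adds prey at the expected binomial rate", {
  sc <- scenario("random", treatment = treatment(reappearance = TRUE))
  st <- init_state(sc, 77)
  set.seed(78)
  for (i in 1:10000) st <- reappearance_step(st)
  expect_lt(abs(st$reappeared["mobile"] - 1000), 60)
  expect_lt(abs(st$reappeared["sedentary"] - 1000), 60)
  expect_equal(length(st$mobile$x), 200 + unname(st$reappeared["mobile"]))
  expect_conserved(st)
})

test_that("reappearance is a no-op when disabled", {
  st <- init_state(scenario("random"), 1)
  expect_identical(reappearance_step(st), st)
})

test_that("new sedentary prey appear in a Moore-neighbour cell of a live one", {
  sc <- scenario("random", treatment = treatment(reappearance = TRUE))
  st <- init_state(sc, 79)
  # a single anchor in a corner cell, so torus adjacency is exercised
  st$sedentary <- list(x = 0.5, y = 0.5, cx = 0L, cy = 0L)
  st$init_n["sedentary"] <- 1L
  set.seed(80)
  for (i in 1:400) {
    before <- length(st$sedentary$x)
    cx0 <- st$sedentary$cx
    cy0 <- st$sedentary$cy
    st <- reappearance_step(st)
    n_new <- length(st$sedentary$x) - before
    if (n_new > 0) {
      ncx <- st$sedentary$cx[before + 1]
      ncy <- st$sedentary$cy[before + 1]
      ddx <- pmin(abs(ncx - cx0), 51 - abs(ncx - cx0))
      ddy <- pmin(abs(ncy - cy0), 51 - abs(ncy - cy0))
      expect_true(any(ddx <= 1 & ddy <= 1 & (ddx + ddy) > 0))
      expect_equal(floor(st$sedentary$x[before + 1]), ncx)
    }
  }
  expect_gt(st$reappeared["sedentary"], 0)
})

test_that("sedentary reappearance is skipped when no anchor survives", {
  sc <- scenario("random", treatment = treatment(reappearance = TRUE))
  st <- init_state(sc, 81)
  st$sedentary <- list(x = numeric(0), y = numeric(0),
                       cx = integer(0), cy = integer(0))
  st$init_n["sedentary"] <- 0L
  set.seed(82)
  for (i in 1:200) st <- reappearance_step(st)
  expect_identical(unname(st$reappeared["sedentary"]), 0L)
  expect_gt(st$reappeared["mobile"], 0)
})

test_that("each step advances the clock by one and conserves prey", {
  sc <- scenario("clumped", ambush_present = TRUE,
                 treatment = treatment("D", "ARS", "prey",
                                       capture_probability = 0.5,
                                       reappearance = TRUE),
                 stop_threshold = 1000L)
  st <- init_state(sc, 90)
  for (i in 1:300) {
    t0 <- st$t
    st <- simulation_step(st)
    expect_identical(st$t, t0 + 1L)
    expect_conserved(st)
  }
  expect_gt(st$active$captured_mobile + st$active$captured_sedentary, 0)
})

test_that("stepping a terminated state is an error", {
  st <- init_state(fast_scenario(), 1)
  while (!st$terminated) st <- simulation_step(st)
  expect_error(simulation_step(st), "terminated")
})

test_that("a speed-doubled mover covers two unit segments per step", {
  # zero max turn makes the trajectory a straight line, so the per-step
  # displacement of a x2 mover must be exactly two cells along its heading
  sc <- scenario("random", treatment = treatment("D", "D", "prey"),
                 directional_max_turn = 0, n_sedentary = 0,
                 stop_threshold = 1000L)
  st <- init_state(sc, 101)
  st$active$x <- 0.5; st$active$y <- 0.5  # park the predator away from prey
  st$mobile <- list(x = c(25, 30), y = c(25, 12), heading = c(0, 90))
  st$init_n["mobile"] <- 2L
  st <- simulation_step(st)
  expect_equal(st$mobile$x, c(27, 30))
  expect_equal(st$mobile$y, c(25, 14))
})

test_that("zero-turn trajectories follow the closed-form torus line", {
  sc <- scenario("random", treatment = treatment("D", "D"),
                 directional_max_turn = 0, n_mobile = 20, n_sedentary = 0,
                 stop_threshold = 1000L)
  st <- init_state(sc, 103)
  x0 <- st$mobile$x; y0 <- st$mobile$y; h <- st$mobile$heading
  ax0 <- st$active$x; ay0 <- st$active$y; ah <- st$active$heading
  for (i in 1:40) st <- simulation_step(st)
  expect_identical(st$active$captured_mobile, 0L)  # no interception occurred
  r <- h * pi / 180
  expect_equal(st$mobile$x, (x0 + 40 * cos(r)) %% 51, tolerance = 1e-9)
  expect_equal(st$mobile$y, (y0 + 40 * sin(r)) %% 51, tolerance = 1e-9)
  expect_equal(st$active$x, (ax0 + 40 * cos(ah * pi / 180)) %% 51,
               tolerance = 1e-9)
  expect_equal(st$active$y, (ay0 + 40 * sin(ah * pi / 180)) %% 51,
               tolerance = 1e-9)
})

test_that("runs are a pure function of scenario and seed", {
  sc <- fast_scenario()
  expect_identical(run_simulation(sc, 7), run_simulation(sc, 7))
})

test_that("runs terminate at the capture threshold with a full ledger", {
  r <- run_simulation(fast_scenario(), 11)
  expect_identical(r$termination, "threshold_reached")
  tot <- r$captured_mobile_active + r$captured_sedentary_active
  expect_gte(tot, 30)
  expect_lte(tot, 32)  # at most one double capture of overshoot per check
  expect_identical(r$captured_mobile_active + r$alive_mobile +
                     r$captured_mobile_ambush, 200L)
  expect_identical(r$captured_sedentary_active + r$alive_sedentary, 200L)
})

test_that("the max_steps cap is reported, not raised", {
  sc <- scenario("random", stop_threshold = 200L, max_steps = 50L)
  r <- run_simulation(sc, 3)
  expect_identical(r$termination, "max_steps")
  expect_identical(r$duration_steps, 50L)
})

test_that("positions stay inside the arena throughout a run", {
  st <- init_state(fast_scenario(), 19)
  for (i in 1:200) {
    if (st$terminated) break
    st <- simulation_step(st)
    expect_true(all(st$mobile$x >= 0 & st$mobile$x < 51 &
                    st$mobile$y >= 0 & st$mobile$y < 51))
    expect_true(st$active$x >= 0 && st$active$x < 51 &&
                st$active$y >= 0 && st$active$y < 51)
  }
})
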