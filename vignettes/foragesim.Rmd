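---
title: "foragesim: model description and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foragesim: model description and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model asks

Does an actively searching predator really end up capturing mostly
*sedentary* prey, as the foraging-mode paradigm predicts? `foragesim`
answers this purely at the level of encounter rates: both prey types are
equally dense, equally catchable, and never react to the predator, so any
asymmetry in what the predator ends up eating comes from geometry and
movement alone. The output of every run is the proportion of mobile prey
among the active predator's captures; 0.5 means no preference.

## World and agents

The arena is a `width × height` grid of unit cells (default 51 × 51) with
continuous agent coordinates. The default boundary is a torus: positions are
reduced modulo the arena dimensions and the heading is unchanged, so there
are no edge effects. A reflecting boundary (`boundary_mode = "reflect"`) is
provided for boundary-sensitivity analyses; it mirrors the offending
coordinate and negates the normal velocity component, which necessarily
breaks the heading-change bound at the moment of a bounce.

Four kinds of agents exist: one active predator (moves, captures both prey
types), an optional ambush predator (never moves, captures mobile prey
only), 200 mobile prey (move), and 200 sedentary prey (never move).
Movers follow a correlated random walk: each sub-step the heading changes by
a draw from Uniform(−τ, +τ) and the agent advances one cell length along the
new heading. τ = 10° is "directional" movement, τ = 120° "nondirectional".

Capture is resolved at the cell level: whenever a predator and prey occupy
the same cell `(floor(x), floor(y))` at a capture check, each co-located
prey independently succumbs with the scenario's capture probability (1.0,
or 0.5 in the uncertain-capture treatments). Captured prey are removed
immediately and cannot be captured twice. All co-located prey are eligible
in the same check — a predator standing among two prey can take both.

## Scheduling

Each time step runs, in order: (1) every live mobile prey takes its unit
sub-steps, with a capture check over the active predator's cell after every
sub-step round; (2) the active predator takes its sub-steps, checking its
cell after each; (3) the ambush predator's single per-step check; (4) the
area-restricted-search timer decrements; (5) reappearance draws; (6) the
stop check, after which the clock advances. Capture is therefore determined
each time the mobile prey or the active predator move, and once per time
step for the ambush predator.

Speed doubling ("prey move twice as fast" / "predator moves twice as fast")
is implemented as two unit sub-steps per time step, each followed by a
capture check — a single two-cell jump would tunnel through an intervening
cell without an encounter.

A run ends when the active predator's total captures reach the stop
threshold (default 200 — half of all prey initially present; only the active
predator's ledger counts) or, as a safety net against degenerate
configurations, at `max_steps` (default 10^6, never reached under the
default catalog).

## Area-restricted search

An ARS predator travels directionally (τ = 10°) until a capture check
involves a sedentary prey; it then turns nondirectionally (τ = 120°) for
`duration = 20` time steps, and every further sedentary encounter resets the
countdown to the full 20 (never additively). This concentrates search effort
inside a patch after the first hit, which is exactly what makes clumped
sedentary prey exploitable.

Two open points were closed as follows:

* **Trigger.** The default trigger is *encounter* (cell co-occupancy with a
  sedentary prey, regardless of capture success), the literal reading of
  switching "after encountering" prey. An `"on_capture"` trigger is provided
  as a config option; the two differ only under 50 % capture.
* **Timing.** The predator's max turn for a whole time step is fixed on step
  entry from the timer's current value ("120° iff the timer is positive
  entering the step"). A trigger raised during the prey phase of step *t*
  therefore first shows in the movement of step *t* + 1, and a single
  trigger yields exactly 20 subsequent nondirectional steps.

## Competition and contested captures

The ambush predator captures mobile prey that wander into its cell. It
ignores sedentary prey: sedentary prey cannot enter its cell after
initialization, and the ambusher functions purely as a competitor for the
mobile-prey pool. When the active predator happens to stand in the ambush
predator's cell at the phase-3 check, each co-located prey is contested:
the prey first survives or succumbs to a single Bernoulli(capture
probability) trial — keeping capture uncertainty independent of predator
identity — and only a captured prey is then credited to one predator by a
fair coin flip. Under certain (100 %) capture the active predator has
already emptied the shared cell in phase 2, so contested captures arise only
in the uncertain-capture treatments.

## Initialization and reappearance

Sedentary prey are placed either uniformly over the continuous arena
("random" pattern) or in a clumped pattern: 8 patch centers uniform over the
arena, 25 prey uniform over the radius-5 disc about each center (square-root
radial sampling; discs wrap across the torus, and the radius constraint
holds in torus distance). Mobile prey and predators are uniform; all mover
headings are i.i.d. uniform on [0, 360), since random positions imply no
preferred orientation.

With reappearance enabled, each time step makes one independent
Bernoulli(0.10) draw per prey type. A new mobile prey appears at a uniform
position with a uniform heading and neither moves nor is capture-checked
until the next step. A new sedentary prey appears at a uniform position
inside one of the eight Moore-neighbour cells (torus-adjacent, chosen
uniformly) of a uniformly chosen live sedentary prey — "a neighbouring cell"
on a square grid is read as the Moore neighbourhood. If no sedentary prey
survives, the draw is skipped silently: there is no anchor to place a
neighbour against.

## The catalog

`build_scenario_table()` expands 18 treatment rows — 9 per spatial pattern —
with the ambush predator absent and present into 36 conditions. The default
predator is directional in the random pattern and uses ARS in the clumped
pattern, so the per-pattern rows are: default, the pattern-crossed predator
mode (ARS under random, fixed-directional under clumped), nondirectional
prey, nondirectional predator, both nondirectional, prey speed ×2, predator
speed ×2, 50 % capture, and reappearance. Identifiers are stable slugs,
`pattern/solo-or-ambush/treatment`, e.g. `clumped/ambush/capture-50`.

## Evaluation

Each condition is replicated 50 times; replicate *r* of an experiment uses
seed `base_seed + r − 1`, making whole experiments bit-reproducible and
execution-order independent. The per-run statistic is the proportion of
mobile prey among the active predator's captures. The 95 % interval is a
percentile bootstrap: 10,000 resamples of the 50 proportions with
replacement, the mean of each resample, and the order statistics at 1-based
ranks `ceiling(0.025·B)` = 250 and `ceiling(0.975·B)` = 9,750 of the sorted
resample means. (Resampled *means* are sorted — a 95 % quantile cannot be
read off a single sorted group of 50 values.) Treatments are called
different when their closed intervals do not overlap; touching endpoints
count as overlap. The bootstrap accepts its own seed and restores the global
RNG state, so evaluation never perturbs simulation streams.

## Numerical and degenerate-case choices

* Headings are normalized to [0, 360) after every update; turning draws are
  exact uniforms, so a max turn of 0 gives perfectly straight torus lines —
  used as a closed-form oracle for the movement engine.
* Cell membership is `floor()` with the half-open convention `[i, i + 1)`.
* A reflecting bounce landing exactly on a wall is nudged one part in 10^12
  inside, keeping the position-containment invariant strict.
* The stop comparator is ≥ threshold (the threshold is exactly the named
  capture count, and the choice shifts a run by at most one capture); it is
  config-exposed for stop-condition sensitivity analyses.
* A run can overshoot the threshold by the size of the final multi-prey
  check, since the stop condition is evaluated once per time step.
* `proportion_mobile` is undefined (an error) at zero total captures, which
  cannot occur in a threshold-terminated run; replicates that hit the
  `max_steps` cap are excluded from summaries with a loud warning.
* Stored run records round the proportion to 6 decimals so the CSV
  round-trips byte-stably; counts are exact integers.

## What the simulation does and does not emulate

The model captures movement-driven encounter rates: directional persistence,
area-restricted search, speed asymmetries, depletion, and exploitation
competition. It deliberately omits prey evasion or any behavioural response,
interference between predators, habitat structure, movement costs, and
birth–death dynamics, and it assumes identical per-encounter catchability of
the two prey types. Passing tests therefore show that the *encounter
geometry* behaves as specified — not that real predators show these
preferences; in the field, detection and subduing differences between prey
types would overlay everything simulated here.

## Problem sizes used by the test suite

Unit tests run the engine at the full 51 × 51 / 400-prey scale but with
reduced stop thresholds (25–60 captures) so each run lasts a few hundred
steps. The full-scale reproduction tests and the acceptance script run the
study design unchanged — 50 replicates × 200-capture threshold per targeted
condition — which takes a few minutes in total. Bootstrap coverage is
checked with 1,000 synthetic Normal samples of size 50 at 1,000 resamples
each; the CI-rank arithmetic is identical at any resample count.

## Known limitations

* The engine is vectorized R; it is comfortably fast for the catalog scale
  (a default run of ~1,500 steps takes well under a second) but is not tuned
  for arenas orders of magnitude larger.
* The reflecting boundary is provided for sensitivity analyses; all default
  catalog results use the torus.
* Only the percentile bootstrap is implemented — no BCa or studentized
  variants, and no formal hypothesis tests, since CI overlap is the
  decision rule.
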