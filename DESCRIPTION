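Package: foragesim
Title: Spatially Explicit Individual-Based Simulation of Predator Foraging Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based, spatially explicit simulation of an actively
    searching predator foraging on mobile and sedentary prey on a toroidal
    arena, optionally competing with a stationary ambush predator. Agents
    perform correlated random walks with configurable directionality and
    speed; the active predator can use area-restricted search, switching to
    tortuous movement after encountering sedentary prey. The package ships
    the full treatment catalog (spatial pattern of sedentary prey, movement
    directionality, speed multipliers, uncertain capture, prey reappearance,
    ambush competition), replicated experiment drivers, percentile-bootstrap
    confidence intervals for the proportion of mobile prey captured, CSV
    input/output, figure regeneration, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
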