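Package: chankin
Title: Kinetics of Substrate Channeling in Two-Enzyme Cascade Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetics of channeled and non-channeled
    Michaelis-Menten two-enzyme cascades. Provides closed-form steady-state
    production velocities, the substrate threshold above which the
    intermediate pool diverges, intermediate pool sizes as a function of the
    degree of channeling, extensions for intermediate degradation and a
    reversible first reaction, stiff ODE integration of the full mixed
    system (free enzymes plus enzyme-enzyme complexes) under batch,
    constant-substrate and constant-feed conditions, channeling phase
    diagrams (steady-state and batch-reactor demarcation curves), and
    Brownian-dynamics estimation of diffusion-limited substrate association
    rates for bead-model enzymes and enzyme-enzyme complexes via the
    Northrup-Allison-McCammon method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
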