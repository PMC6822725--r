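Package: undulate
Title: Muscle-Structure-Hydrodynamics Model of Undulatory Swimming Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled model of steady undulatory swimming for elongated
    aquatic organisms. Combines a Hill-type muscle model under cyclic
    (sinusoidal) contraction, Lighthill slender-body hydrodynamics with
    rigid-body recoil balance, and an Euler-Bernoulli beam description of
    body bending to compute the steady swimming speed, mechanical and
    metabolic power, cost of transport and the muscle, internal,
    hydrodynamic and total efficiencies of a swimmer of given shape,
    size and motion. Includes a two-objective (maximum sustained speed
    versus minimum cost of transport) evolutionary optimizer over shape
    and motion parameters with Pareto-front extraction and body-mass
    scans across the laminar-turbulent drag transition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
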