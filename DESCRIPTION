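Package: abetaoc
Title: Optimal Control of Amyloid-Beta Monomer and Oligomer Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A five-population kinetic model of amyloid-beta aggregation
    (monomers, proto-oligomers of length 2-4, and oligomers) with
    polymerization, depolymerization, fragmentation, concatenation and
    degradation, coupled to four optimal-control treatment formulations
    (monomer-targeting, oligomer-targeting, both independently, or a single
    shared treatment). Treatment schedules that minimize a weighted objective
    functional are computed with the forward-backward sweep method driven by
    the Pontryagin adjoint system. Includes a-priori solution bounds,
    oligomer sandwich bounds, equilibrium and linear stability analysis,
    scenario presets, parameter sweeps and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
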