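Package: kinebundle
Title: Continuum Model of Kinetochore-Driven Microtubule Bundling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the rearrangement of spindle-midplane microtubules from a
    loose crosslinked network into discrete bundles anchored at kinetochores.
    Implements a one-dimensional Ginzburg-Landau free energy with point
    attractors on a periodic ring, conserved (Cahn-Hilliard-type) density
    dynamics with microtubule turnover, an even-power-series steady-state
    solver with a delta-function slope-jump boundary condition, linear
    stability diagnostics, effective-free-energy analysis of kinetochore
    lattice deformations, estimation of the model parameters from measured
    biological quantities, and generators of synthetic fluorescence rim
    traces with Poisson photon noise together with peak-based observables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
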