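Package: clotsim
Title: Continuum Simulation of Platelet Aggregation and Flow-Mediated Coagulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained two-dimensional structured-grid finite-volume
    simulator of platelet aggregation and surface-triggered coagulation under
    flow. Blood plasma is modelled as an incompressible Newtonian fluid obeying
    the Navier-Stokes-Brinkman equations with a Carman-Kozeny permeability that
    depends on the local bound-platelet fraction; platelets are continuum number
    densities transported with a hindered flux that enforces a hard packing
    limit via downwind/local-maximum face interpolation; ADP secretion from
    newly bound platelets uses a finite-memory history integral; and a reduced
    twelve-species coagulation cascade with platelet-surface binding, positive
    feedback, enzyme inhibition and reactive injured-wall boundary conditions is
    coupled to transport by a fractional-step scheme with coupled Runge-Kutta
    reaction sub-stepping. Includes a channel thrombosis scenario generator,
    VTK/CSV output writers and clot growth metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
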