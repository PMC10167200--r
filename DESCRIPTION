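Package: riisvalve
Title: Parametric Aortic Valve Geometry and Resistive Immersed Surface Flow Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds subject-specific open aortic-valve geometries from a small set
    of per-leaflet scalar parameters (power-law leaflet and bending curves, quadratic
    and cubic Bezier sinus/symmetry curves, Coons bilinear patch surfaces), converts
    them into a resistive immersed implicit surface (RIIS) penalty field on a
    tetrahedral cylinder mesh, and runs penalized incompressible Navier-Stokes
    simulations (monolithic P1bubble/P1 mixed finite elements, backward Euler,
    Temam and backflow stabilization) to compute transvalvular hemodynamics:
    peak jet velocity, transvalvular pressure drop, and their relation to the
    simplified Bernoulli estimate used in echocardiography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
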