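Package: coraltherm
Title: Thermal Microenvironments of Corals by Finite-Volume Heat and Flow
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the thermal microenvironment of hemispherical and
    branching corals in a laboratory flow chamber.  Couples laminar
    incompressible channel flow with Darcy-Forchheimer porous sinks in the
    coral tissue and skeleton to a conjugate energy equation with an
    irradiance surface source, solved on a graded Cartesian grid with a
    SIMPLE-type finite-volume scheme.  Includes a closed-form lumped
    heat-balance model (steady surface warming and thermal time constant),
    material-property closures for porous coral skeletons, species presets,
    and scripted replications of steady irradiance sweeps, dark-light
    transients, flow comparisons and bulk-density sensitivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
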