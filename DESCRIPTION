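Package: tortuflow
Title: Hemodynamics of Idealized Tortuous Coronary Arteries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Parametric construction of idealized two-dimensional tortuous
    coronary vessel geometries described by a tortuosity angle and a
    tortuosity count, structured body-fitted quadrilateral meshing of the
    lumen, a finite-volume incompressible laminar Navier-Stokes solver with
    SIMPLE pressure-velocity coupling (steady and pulsatile, first-order
    upwind convection, Rhie-Chow face-flux interpolation), cardiac-cycle
    boundary waveforms, and post-processing of inlet-to-outlet pressure drops
    over a tortuosity-angle by tortuosity-count design, including closed-form
    and discrete channel-flow oracles for solver verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
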