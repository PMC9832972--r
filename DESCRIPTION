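Package: fibershape
Title: Equilibrium Shapes of Tissues Stabilized by Contractile Surface Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes equilibrium shapes of axisymmetric fluid-like bodies
    (such as growing microtissues spanning two coaxial disks) whose surface
    stress is carried by contractile fibers rather than an isotropic surface
    tension. Mechanical equilibrium forces the fibers onto geodesics of
    constant normal curvature, which generalizes the Young-Laplace law and the
    constant-mean-curvature (Delaunay) surfaces it selects. The package
    provides the differential-geometry kernels for surfaces of revolution, the
    governing fiber ODE systems in cylindrical and Cartesian form, a shooting
    solver for the disk boundary conditions, closed-form reference shapes
    (sphere, cylinder, hyperboloid, torus segments, catenoid, stacked spheres,
    Delaunay family), phase-diagram sweeps with pressure-sign classification,
    tissue pressure and tension estimates, and CSV/OBJ export with a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
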