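# fibershape

Equilibrium shapes of axisymmetric fluid-like bodies — growing microtissues
spanning two coaxial disks — whose surface stress is carried by **contractile
fibers** rather than an isotropic surface tension.

## The science

A growing tissue flows like a fluid, so its shape is set by its surface
stress. With an isotropic surface stress $\gamma_s$ the Young–Laplace law
$p = -2\gamma_s H$ selects constant-mean-curvature (Delaunay) surfaces. But
imaging shows that the near-surface actin stress fibers of such tissues are
strongly aligned, winding helically around the tissue: the surface is
mechanically anisotropic.

In the fiber-dominated limit, static equilibrium imposes two conditions on
every fiber:

1. the fiber's principal normal must be colinear with the surface normal
   ($e_p = e_n$) — fibers follow **geodesics**;
2. the fiber's normal curvature $\kappa_T = 1/R_T$ must be **constant**, so
   that the pressure $p = d\,\sigma_T/R_T$ generated by a contractile layer
   (thickness $d$, fiber stress $\sigma_T$) is constant in the fluid.

For a surface of revolution $X(\theta,z) = (g\cos\theta, g\sin\theta, z)$
this yields

$$
g'' = \frac{1+g'^2}{g\,(Kg^2-1)}\Big(1 - K\kappa_T g^3\sqrt{1+g'^2}\Big),
\qquad
\theta' = \frac{1}{g}\sqrt{\frac{1+g'^2}{Kg^2-1}},
\qquad
K = \frac{1}{g_0^2\sin^2\mu_0},
$$

with neck radius $g_0$, fibril angle $\mu_0$ at the neck, and Clairaut's
relation $g\sin\alpha = g_0\sin\mu_0$ as first integral. The package solves
the boundary-value problem $g(\pm L/2) = R$ by shooting on $\kappa_T$,
provides the closed-form members of the family (cylinder, one-sheet
hyperboloid, spherical segments and stacks, torus segments), the competing
Delaunay (constant-$H$) family, phase-diagram sweeps with pressure-sign
classification, and the pressure/tension estimates.

## Worked example

```r
library(fibershape)

# a necked tissue bridge: neck radius 0.6, fibril angle 35 degrees,
# disks of radius 1 at z = +/- 0.625
res <- solve_kappa(g0 = 0.6, mu0 = 35)
res
#> <shooting_result> status: converged
#>    kappa_T = -0.6809035   |g(L/2) - R| = 3.120681e-10
glance(res$solution)
#> # A tibble: 1 x 9
#>      g0   mu0 kappa_T     K  H_neck pressure_sign boundary_residual chirality status
#>   <dbl> <dbl>   <dbl> <dbl>   <dbl>         <dbl>             <dbl> <chr>     <chr>
#> 1   0.6    35  -0.681  8.44 -0.0826            -1         -3.12e-10 right     ok
```

The solved fiber curvature is negative: at this neck the contractile fibers
*reduce* the pressure inside the tissue (growth-promoting). `H_neck` is the
mean curvature at the neck — not constant over the surface, unlike a
Delaunay shape. The fiber paths and the surface follow from the solution:

```r
autoplot(res$solution)              # meridian silhouette
fiber_family(res$solution, 8)       # eight congruent helical fibers
export_mesh(res$solution, "neck.obj", n_fibers = 8)

# where does the 35-degree family stop pulling the pressure down?
zero_pressure_neck("fiber", mu0 = 35)    # 0.8991553  (hyperboloid locus)
zero_pressure_neck("isotropic")          # 0.7037334  (catenoid neck)

# physical pressure for a 10 um myofibroblast layer at 2 kPa on a fiber
# curvature radius of 1 mm
fiber_pressure("10um", "2kPa", "1mm")    # 20 Pa
effective_tension("2kPa", "10um")        # 20 mN/m
```

The two `zero_pressure_neck()` numbers summarize the model's main
prediction: aligned fibers at the experimentally observed ~35° angle keep
the tissue pressure negative up to a neck radius of about 0.9, whereas an
isotropic surface stress turns it positive already at about 0.7.

A thin CLI wraps the same functions
(`inst/cli/fibershape.R solve --g0 0.6 --mu0 35 --out neck`), with `sweep`,
`delaunay`, `pressure` and `mesh` subcommands.

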