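---
title: "Equilibrium shapes of tissues stabilized by contractile surface fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium shapes of tissues stabilized by contractile surface fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibershape)
```

## The model

Growing microtissues behave, over the timescale of growth, like viscous
fluids: shear stresses relax and only an isostatic pressure remains, so the
equilibrium shape is set by the state of stress in a thin surface layer. For
an isotropic surface stress $\gamma_s$ the Young–Laplace relation
$p = -\gamma_s (1/R_1 + 1/R_2) = -2\gamma_s H$ selects constant-mean-curvature
shapes — for bodies of revolution, the classical Delaunay family (sphere,
cylinder, catenoid, unduloid, nodoid).

Fluorescence imaging of fibroblast- and osteoblast-derived microtissues
grown between two coaxial disks shows something different: the near-surface
actin stress fibers are strongly aligned and wind helically around the
tissue. `fibershape` implements the equilibrium theory for this *anisotropic*
limit, in which the entire surface load is carried by a family of parallel
contractile fibers:

* **Force direction.** The resultant of a tensed fiber lies along its
  principal normal $e_p$ (in the osculating plane); the pressure acts along
  the surface normal $e_n$. Equilibrium of the surface patch therefore
  requires $e_p = e_n$, i.e. $e_p \times e_n \equiv 0$: the fibers have zero
  geodesic curvature — they are **geodesics** of the surface.
* **Force magnitude.** With a contractile layer of thickness $d$ under
  fiber stress $\sigma_T$, membrane equilibrium reduces to
  $p = d\,\sigma_T / R_T$, with $R_T$ the fiber's curvature radius. A
  constant interior pressure and constant fiber tension then force the
  normal curvature $\kappa_T = 1/R_T$ to be **constant along each fiber**.

For a surface of revolution $X(\theta, z) = (g(z)\cos\theta,
g(z)\sin\theta, z)$ carrying fibers $\theta = \theta(z) + \theta_0$, these
two conditions reduce to the coupled system

$$
g'' \;=\; \frac{1 + g'^2}{g\,(K g^2 - 1)}
  \left(1 - K\,\kappa_T\, g^3 \sqrt{1 + g'^2}\right),
\qquad
\theta' \;=\; \frac{1}{g}\sqrt{\frac{1 + g'^2}{K g^2 - 1}} ,
$$

where the $\theta'$ equation alone is the classical geodesic equation on a
surface of revolution and the $g''$ equation enforces the constant normal
curvature. The integration constant follows from Clairaut's relation at the
neck: writing $g(0) = g_0$, $g'(0) = 0$ and $\mu_0$ for the fibril angle
between fiber and meridian at the neck, $K = 1/(g_0^2 \sin^2 \mu_0)$ and
$g(z)\sin\alpha(z) = g_0 \sin\mu_0$ along the whole fiber.

### Boundary-value problem

The experimental geometry is a capillary bridge: the tissue spans two
coaxial disks of radius $R$ at $z = \pm L/2$, so $g(\pm L/2) = R$. Working
in units of $R$ the package defaults to $R = 1$, $L = 1.25$ (disks at
$z = \pm 0.625$). The literature describing this setup states the aspect
ratio inconsistently in two places ($2L/R = 1.25$ versus $L = 1.25$ at
$R = 1$); we adopt $R = 1$, $L = 1.25$, which uniquely reproduces the three
quantitative landmarks of that geometry (the 58° single-sphere limit, the
catenoid neck at $\approx 0.7$, and the 35° zero-pressure neck at
$\approx 0.9$), and keep both values configurable.

`fiber_profile()` integrates the system from the neck conditions
$g(0) = g_0$, $g'(0) = 0$, $\theta(0) = 0$; `solve_kappa()` imposes the
outer boundary by shooting on $\kappa_T$. Following the numerical procedure
that turned out most robust, $g_0$ and $\mu_0$ are fixed and $\kappa_T$ is
the shooting unknown.

### Sign conventions

The printed derivations leave the sign of $\kappa_T$ to a supplement, and
the Cartesian and cylindrical forms of the governing equations are mutually
consistent only up to a global sign of $\kappa_T$. The package fixes one
convention everywhere: the outward normal points away from the axis, and
$\kappa_T > 0$ when the fiber's principal normal points into the tissue
interior. Consequently the single spherical segment solves the meridian
equation with $\kappa_T = +1/\rho$ (positive pressure), necked shapes have
$\kappa_T < 0$ (negative pressure, growth-promoting), and the hyperboloid's
straight rulings sit exactly at $\kappa_T = 0$. The Cartesian oracle
(`fiber_cartesian()`) maps its curvature argument onto this convention
internally, so both formulations accept the same `kappa_T`. Mean curvature
uses $H = +1/\rho$ for a sphere and $H = 0$ for a catenoid, so that
$H_{neck} = (1/g_0 - g''(0))/2$ at the symmetry plane.

Both fiber chiralities solve the model identically; `fiber_profile()` winds
right-handed by default with `chirality = "left"` for the mirror image.

## Reference shapes and oracles

Closed-form members of the family anchor both the phase diagrams and the
test suite:

* **Cylinder** ($g \equiv R$): fixed point of the meridian equation with
  $\kappa_T = \sin^2\mu_0 / R$.
* **One-sheet hyperboloid** ($g^2 = g_0^2 + m z^2$): straight rulings,
  $\kappa_T = 0$, ruling angle $\mu_0 = \arctan\sqrt{m}$; the zero-pressure
  locus of the fiber model.
* **Single spherical segment** ($\rho = \sqrt{R^2 + (L/2)^2}$): great-circle
  fibers with $\kappa_T = 1/\rho$, admissible for fibril angles up to
  $\arccos((L/2)/\rho) \approx 58°$ in the reference geometry.
* **Torus segments**: the meridian-fiber limit $\mu_0 = 0$, circular arcs
  through the boundary circles.
* **Stacked spherical segments** ($n = 2, 3$): continuous but not
  differentiable at their joints; limit cases toward which solutions tend at
  large positive $\kappa_T$. Physically the segments must share one sphere
  radius (one $\kappa_T$ across the stack); with that constraint an
  equal-height three-segment stack would degenerate to a single point of the
  family, so the stacks are parameterized by the neck/apex radius with the
  joint position following from the boundary conditions.
* **Delaunay family** (`delaunay_solve()`): the isotropic competitor.  The
  CMC meridian is integrated in arc length ($z' = \cos\psi$,
  $g' = \sin\psi$, $\psi' = \cos\psi/g - 2H$), which remains regular through
  vertical tangents of nodoid branches, and $H$ is found by shooting. The
  first integral $g/\sqrt{1+g'^2} - H g^2 = B$ is monitored as an invariant.

## Numerical choices

* Integration uses `deSolve::lsodar` at `rtol = 1e-10`, `atol = 1e-12`
  (scans use cheaper tolerances before Brent polishing at `tol = 1e-10`).
* The singular set $K g^2 = 1$ — where a fiber runs tangent to a parallel
  circle — and pinch-off ($g \to 0$) or slope blow-up are detected by root
  functions; the failure position and mode are reported rather than stepped
  over. The singular margin ($10^{-7}$) and slope cap ($|g'| = 10^3$) stop
  the integrator while the step size is still healthy; converged solutions
  stay orders of magnitude away from both thresholds (the closest approach,
  $B \approx 3\times10^{-4}$, occurs at the 58° sphere limit).
* The shooting residual is $g(L/2) - R$ where integration reaches the
  boundary and a signed distance-to-failure penalty where it does not, so
  sign-change brackets remain informative across failure regions. All roots
  in the bracket (default $\kappa_T \in [-20, 20]$, 97 scan nodes) are
  polished and reported; the smallest $|\kappa_T|$ is flagged primary.
* Profiles are stored with solver-supplied derivatives and evaluated by
  piecewise-cubic Hermite interpolation that honours those slopes
  (interpolation error $\sim 10^{-11}$ on the default 201-node half-grid).
  Curvature below $10^{-9}$ marks a straight segment: the Frenet frame is
  then reported as undefined instead of numerically noisy.
* Sweeps (`sweep_iso_mu0()`) sort and de-duplicate their grids, then
  continue each iso-angle branch in $g_0$ with a warm-started bracket,
  falling back to the full scan when continuation loses the root. This
  keeps results independent of input order while avoiding a full 97-node
  scan at every grid point.
* `mu0 = 90°` is excluded ($K g_0^2 = 1$ at the start point: the "fiber"
  degenerates to the neck circle); `mu0 = 0` is dispatched to the
  torus/cylinder closed forms.

## What the sweeps show

```{r, eval = FALSE}
sw <- sweep_iso_mu0(mu0 = c(0, 20, 35, 50), g0 = seq(0.3, 1.17, by = 0.02))
plot_phase_diagram(sw)                      # (kappa_T, g0) plane
autoplot(sw, x_var = "H_neck")              # (H_neck, g0) plane
```

In the $(\kappa_T, g_0)$ plane every iso-angle curve with $\mu_0 < 58°$
passes through the single-sphere point $(1/\rho, \rho)$, the curves cross
the cylinder line at $(\sin^2\mu_0, 1)$, and their $\kappa_T = 0$ crossings
lie on the analytic hyperboloid relation
$g_0 = \sqrt{R^2 - \tan^2\mu_0\,(L/2)^2}$. The pressure interpretation:
necked shapes ($\kappa_T < 0$) are stabilized by fibers that *reduce* the
interior pressure and thereby favour growth, up to a neck radius of
$\approx 0.9$ at a 35° fibril angle — whereas an isotropic surface stress
turns pressure positive already at the catenoid neck $\approx 0.7$. This
difference is the main mechanobiological payoff of the anisotropic model.

`delaunay_proximity()` quantifies how close the 35° fiber family runs to the
Delaunay family: over $g_0 \in [0.4, 0.7]$ the sup-norm meridian deviation
stays below a few per cent of the neck radius, consistent with the
observation that the two are experimentally indistinguishable — and with the
measured fibril angles of 30–40°.

## Mechanics and units

`fiber_pressure()`, `young_laplace()`, `membrane_pressure()` and
`effective_tension()` expose the pressure laws in SI units. Arguments may be
numeric (SI) or strings with explicit unit suffixes (`"2kPa"`, `"10um"`,
`"1mm"`); a unit of the wrong dimension raises an error, so kPa and Pa
cannot be mixed silently. The printed isotropic law carries the classical
minus sign, while the membrane form is its oppositely oriented counterpart
(`membrane_pressure(g, g, R1, R2) == -young_laplace(g, R1, R2)`); the
package treats $p$ as interior minus exterior pressure throughout.
Myofibroblast-scale stresses of 2–5 kPa acting through the top 10 µm of the
tissue convert to effective tensions of 20–50 mN/m, one to two orders above
reported isotropic tissue surface tensions (0.1–3 mN/m) — the regime in
which the fiber-dominated limit is the right idealization.

## Scope and limitations

* Only rotationally symmetric surfaces and symmetric solutions
  ($g(-z) = g(z)$, $\theta(-z) = -\theta(z)$) are computed; the equilibrium
  conditions themselves are not restricted to this symmetry.
* The tissue interior is an inviscid fluid: no bulk constitutive model, no
  time-dependent (viscous) shape evolution.
* Fibers transfer no load laterally; intermediate isotropic/anisotropic
  mixtures are outside the model.
* The interior of the region between the two- and three-segment stack
  curves is not modelled; the stacks themselves are non-smooth limit cases.
* Test problem sizes: solver tests run single solves and short sweeps; the
  full phase-diagram sweep used in the acceptance suite covers nine fibril
  angles by ~110 neck radii, a few minutes on one core.
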