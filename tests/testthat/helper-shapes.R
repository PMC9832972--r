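# Shared geometry for the reference experiment: disks of radius 1 at
# z = +/- 0.625.
REF_R <- 1
REF_L <- 1.25
REF_RHO <- sqrt(REF_R^2 + (REF_L / 2)^2)

# analytic great circle on the single spherical segment, with exact
# derivatives with respect to the parameter t (radians along the circle)
great_circle_pts <- function(rho, mu0_deg, t_range = c(-0.55, 0.55),
                             n = 101) {
  mu <- mu0_deg * pi / 180
  t <- seq(t_range[1], t_range[2], length.out = n)
  tibble::tibble(
    t = t,
    x = rho * cos(t), y = rho * sin(t) * sin(mu), z = rho * sin(t) * cos(mu),
    xp = -rho * sin(t), yp = rho * cos(t) * sin(mu),
    zp = rho * cos(t) * cos(mu),
    xpp = -rho * cos(t), ypp = -rho * sin(t) * sin(mu),
    zpp = -rho * sin(t) * cos(mu))
}

# planar circle of radius r (in the z = z0 plane), exact derivatives
circle_pts <- function(r, z0 = 0, n = 101, t_range = c(0, 1.5)) {
  t <- seq(t_range[1], t_range[2], length.out = n)
  tibble::tibble(
    t = t, x = r * cos(t), y = r * sin(t), z = rep(z0, n),
    xp = -r * sin(t), yp = r * cos(t), zp = rep(0, n),
    xpp = -r * cos(t), ypp = -r * sin(t), zpp = rep(0, n))
}

# meridian of a profile at fixed theta, derivatives from the profile
meridian_pts <- function(profile, theta = 0.3, n = 101, pad = 0.01) {
  zr <- range(profile$z)
  z <- seq(zr[1] + pad, zr[2] - pad, length.out = n)
  g <- profile_eval(profile, z)
  gp <- profile_eval(profile, z, 1)
  gpp <- profile_eval(profile, z, 2)
  tibble::tibble(
    x = g * cos(theta), y = g * sin(theta), z = z,
    xp = gp * cos(theta), yp = gp * sin(theta),
    xpp = gpp * cos(theta), ypp = gpp * sin(theta))
}

expect_unit_vectors <- function(vx, vy, vz, tol = 1e-12) {
  expect_lt(max(abs(sqrt(vx^2 + vy^2 + vz^2) - 1)), tol)
}
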