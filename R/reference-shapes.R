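#' One-sheet hyperboloid through the boundary circles
#'
#' The zero-curvature fiber solution: straight rulings. The meridian obeys
#' \eqn{g^2 = g_0^2 + m z^2} with \eqn{m = (R^2 - g_0^2)/(L/2)^2}, and the
#' rulings cross the waist at angle \eqn{\mu_0 = \arctan\sqrt{m}} from the
#' axis. As \eqn{g_0 \to R} the surface degenerates to the cylinder
#' (\eqn{\mu_0 \to 0}).
#'
#' @param g0 Neck (waist) radius, \eqn{0 < g_0 < R}.
#' @param R Boundary disk radius.
#' @param L Disk separation.
#' @param n Profile grid nodes.
#' @return A list with `profile` (a [profile_curve()]), `mu0` (ruling angle,
#'   degrees), `m` and `kappa_T = 0`.
#' @export
hyperboloid_shape <- function(g0, R = 1, L = 1.25, n = 201) {
  if (g0 <= 0 || g0 >= R) {
    stop("need 0 < g0 < R for a necked hyperboloid through the boundary",
         call. = FALSE)
  }
  m <- (R^2 - g0^2) / (L / 2)^2
  gf <- function(z) sqrt(g0^2 + m * z^2)
  gp <- function(z) m * z / gf(z)
  gpp <- function(z) m * g0^2 / gf(z)^3
  list(profile = profile_from_function(gf, c(-L / 2, L / 2), gp, gpp, n = n),
       mu0 = atan(sqrt(m)) * 180 / pi, m = m, kappa_T = 0)
}

#' Straight ruling of a one-sheet hyperboloid
#'
#' The line \eqn{(g_0, \sqrt{m}\,z, z)} lies on the hyperboloid
#' \eqn{x^2 + y^2 = g_0^2 + m z^2}: a zero-curvature fiber.
#'
#' @inheritParams hyperboloid_shape
#' @return A tibble of 3D points on \eqn{z \in [-L/2, L/2]}.
#' @export
hyperboloid_ruling <- function(g0, R = 1, L = 1.25, n = 201) {
  m <- (R^2 - g0^2) / (L / 2)^2
  z <- seq(-L / 2, L / 2, length.out = n)
  tibble::tibble(x = rep(g0, n), y = sqrt(m) * z, z = z)
}

#' Single spherical segment through the boundary circles
#'
#' The sphere of radius \eqn{\rho = \sqrt{R^2 + (L/2)^2}} with its equator at
#' the symmetry plane. Its fibers are great circles with
#' \eqn{\kappa_T = 1/\rho}; a great circle crossing the equator at fibril
#' angle \eqn{\mu_0} reaches \eqn{|z| = \rho\cos\mu_0}, so it stays between
#' the disks only for \eqn{\mu_0 \le \arccos((L/2)/\rho)} — the largest
#' equator-crossing angle for which the single-segment solution exists.
#'
#' @inheritParams hyperboloid_shape
#' @return A list with `profile`, `rho`, `kappa_T` and `mu_max` (degrees).
#' @export
sphere_segment <- function(R = 1, L = 1.25, n = 201) {
  stopifnot(R > 0, L > 0)
  rho <- sqrt(R^2 + (L / 2)^2)
  gf <- function(z) sqrt(rho^2 - z^2)
  gp <- function(z) -z / gf(z)
  gpp <- function(z) -rho^2 / gf(z)^3
  list(profile = profile_from_function(gf, c(-L / 2, L / 2), gp, gpp, n = n),
       rho = rho, kappa_T = 1 / rho, mu_max = acos((L / 2) / rho) * 180 / pi)
}

#' Great-circle fiber on the single spherical segment
#'
#' @param rho Sphere radius.
#' @param mu0 Equator-crossing angle from the meridian, degrees.
#' @param t_range,n Parameter range (radians along the circle) and samples.
#' @return A tibble of 3D points with parameter column `t`.
#' @export
great_circle <- function(rho, mu0, t_range = c(-1, 1), n = 201) {
  mu0r <- mu0 * pi / 180
  t <- seq(t_range[1], t_range[2], length.out = n)
  tibble::tibble(t = t, x = rho * cos(t), y = rho * sin(t) * sin(mu0r),
                 z = rho * sin(t) * cos(mu0r))
}

# the cylinder as a (trivial) fiber solution object
cylinder_solution <- function(R = 1, L = 1.25, mu0 = 0, n = 201) {
  prof <- profile_from_function(function(z) rep(R, length(z)),
                                c(-L / 2, L / 2),
                                function(z) rep(0, length(z)),
                                function(z) rep(0, length(z)), n = n)
  kap <- sin(mu0 * pi / 180)^2 / R
  structure(list(status = "ok", data = NULL, profile = prof, g0 = R,
                 mu0 = mu0, kappa_T = kap,
                 K = if (mu0 > 0) k_from_boundary(R, mu0) else Inf,
                 R = R, L = L, chirality = "right", H_neck = 0.5 / R,
                 pressure_sign = sign(kap), boundary_residual = 0),
            class = "fiber_solution")
}

#' Stacked spherical segments (limit-case solutions)
#'
#' Stacks of `n` spherical segments of a common radius (a single fiber
#' curvature \eqn{\kappa_T} across the stack), continuous but not
#' differentiable at the joints — limit cases of the shooting family as
#' \eqn{\kappa_T} grows. For `n = 2` the joint is at \eqn{z = 0} and `g0` is
#' the joint radius; for `n = 3` the central segment is symmetric about the
#' equator and `g0` is its apex radius (equal to the sphere radius). Both
#' one-parameter families terminate at the single-segment sphere.
#'
#' @param n 1, 2 or 3 segments.
#' @param g0 Neck/apex radius parameterizing the family (ignored for
#'   `n = 1`).
#' @inheritParams hyperboloid_shape
#' @param n_grid Profile nodes.
#' @return A list with the piecewise `profile`, `g0`, `kappa_T`, the sphere
#'   radius `rho`, joint positions `joints` and `limit_case` flag.
#' @export
stacked_spheres <- function(n, R = 1, L = 1.25, g0 = NULL, n_grid = 401) {
  if (!n %in% 1:3) stop("only stacks of 1, 2 or 3 segments are supported",
                        call. = FALSE)
  half <- L / 2
  if (n == 1) {
    ss <- sphere_segment(R, L, n_grid)
    return(list(profile = ss$profile, g0 = ss$rho, kappa_T = ss$kappa_T,
                rho = ss$rho, joints = numeric(0), limit_case = FALSE))
  }
  if (is.null(g0)) stop("g0 is required for n > 1 (one-parameter family)",
                        call. = FALSE)
  if (n == 2) {
    zc <- (half^2 - g0^2 + R^2) / L
    if (zc < 0) stop("g0 too large for a two-segment stack", call. = FALSE)
    rho <- sqrt(g0^2 + zc^2)
    gf <- function(z) sqrt(pmax(rho^2 - (abs(z) - zc)^2, 0))
    gp <- function(z) -sign(z) * (abs(z) - zc) / gf(z)
    gpp <- function(z) {
      u <- abs(z) - zc
      -1 / gf(z) - u^2 / gf(z)^3
    }
    joints <- 0
  } else {
    rho <- g0
    if (g0 < R || g0 > sqrt(R^2 + half^2)) {
      stop("three-segment stacks require R <= g0 <= sqrt(R^2 + (L/2)^2)",
           call. = FALSE)
    }
    a <- (half - sqrt(g0^2 - R^2)) / 2
    gf <- function(z) {
      u <- ifelse(abs(z) <= a, abs(z), abs(z) - 2 * a)
      sqrt(pmax(rho^2 - u^2, 0))
    }
    gp <- function(z) {
      u <- ifelse(abs(z) <= a, abs(z), abs(z) - 2 * a)
      -sign(z) * u / gf(z)
    }
    gpp <- function(z) {
      u <- ifelse(abs(z) <= a, abs(z), abs(z) - 2 * a)
      -1 / gf(z) - u^2 / gf(z)^3
    }
    joints <- c(-a, a)
  }
  zg <- seq(-half, half, length.out = n_grid)
  prof <- profile_curve(zg, gf(zg), gp(zg), gpp(zg),
                        funs = list(g = gf, g_prime = gp,
                                    g_double_prime = gpp),
                        smooth = FALSE)
  attr(prof, "joints") <- joints
  list(profile = prof, g0 = g0, kappa_T = 1 / rho, rho = rho,
       joints = joints, limit_case = TRUE)
}

#' Torus-segment profile: the meridian-fiber limit
#'
#' At \eqn{\mu_0 = 0} the fibers are meridians, which must then be planar
#' arcs of constant curvature: the profile is a circular arc through
#' \eqn{(0, g_0)} (apex, \eqn{g'(0) = 0}) and \eqn{(\pm L/2, R)} — a segment
#' of a torus. \eqn{\kappa_T = 1/(g_0 - y_0)} is signed: positive for bulged
#' segments (\eqn{g_0 > R}), negative for necked ones.
#'
#' @inheritParams hyperboloid_shape
#' @return A list with `profile`, `kappa_T`, arc radius `r_arc` and centre
#'   offset `y0`.
#' @export
torus_segment <- function(g0, R = 1, L = 1.25, n = 201) {
  stopifnot(g0 > 0)
  if (abs(g0 - R) < 1e-12) {
    stop("g0 = R is the cylinder limit (infinite arc radius)", call. = FALSE)
  }
  half <- L / 2
  y0 <- (g0^2 - R^2 - half^2) / (2 * (g0 - R))
  r_arc <- abs(g0 - y0)
  s <- sign(g0 - y0)
  gf <- function(z) y0 + s * sqrt(r_arc^2 - z^2)
  gp <- function(z) -s * z / sqrt(r_arc^2 - z^2)
  gpp <- function(z) -s * r_arc^2 / (r_arc^2 - z^2)^1.5
  if (min(gf(c(0, half))) <= 0) {
    stop("no positive-radius arc through the constraints", call. = FALSE)
  }
  list(profile = profile_from_function(gf, c(-half, half), gp, gpp, n = n),
       kappa_T = s / r_arc, r_arc = r_arc, y0 = y0)
}

#' Catenoid neck radius through the boundary circles
#'
#' Solves \eqn{c \cosh((L/2)/c) = R} for the catenoid
#' \eqn{g = c\cosh(z/c)} spanning the two disks. The standard catenary
#' bifurcation yields two roots; the larger (stable branch) is primary.
#'
#' @inheritParams hyperboloid_shape
#' @return A list with `c` (primary root), `roots` (both, ascending) and
#'   `profile` for the primary root.
#' @export
catenoid_neck <- function(R = 1, L = 1.25, n = 201) {
  half <- L / 2
  f <- function(c) c * cosh(half / c) - R
  lo <- half / 30  # f(lo) is astronomically positive but still finite
  opt <- stats::optimize(f, c(lo, R))
  if (opt$objective > 0) {
    stop("no catenoid spans the boundary circles (L too large for R)",
         call. = FALSE)
  }
  r1 <- stats::uniroot(f, c(lo, opt$minimum), tol = 1e-14)$root
  r2 <- stats::uniroot(f, c(opt$minimum, R), tol = 1e-14)$root
  cc <- r2
  gf <- function(z) cc * cosh(z / cc)
  gp <- function(z) sinh(z / cc)
  gpp <- function(z) cosh(z / cc) / cc
  list(c = cc, roots = c(r1, r2),
       profile = profile_from_function(gf, c(-half, half), gp, gpp, n = n))
}

# arc-length ODE for constant-mean-curvature meridians:
# z' = cos(psi), g' = sin(psi), psi' = cos(psi)/g - 2H
delaunay_ode_func <- function(s, y, parms) {
  list(c(cos(y[3]), sin(y[3]), cos(y[3]) / y[2] - 2 * parms$H))
}

delaunay_residual <- function(H, g0, R, L, s_max, rtol = 1e-10,
                              atol = 1e-12) {
  out <- try(deSolve::lsodar(
    y = c(z = 0, g = g0, psi = 0), times = c(0, s_max),
    func = delaunay_ode_func, parms = list(H = H),
    rootfunc = function(s, y, parms) {
      c(y[1] - L / 2, y[2] - 1e-6, abs(y[3]) - 2.5 * pi)
    },
    rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error")) return(-2)
  fin <- out[nrow(out), ]
  if (abs(fin[2] - L / 2) < 1e-8) return(fin[3] - R)
  sign(fin[3] - R) * (1 + max(0, L / 2 - fin[2]) / L)
}

#' Delaunay (constant-mean-curvature) surface through the boundary circles
#'
#' Shoots on the mean curvature \eqn{H} so that the axisymmetric CMC meridian
#' with a symmetric neck \eqn{g(0) = g_0,\ g'(0) = 0} satisfies
#' \eqn{g(L/2) = R}. The meridian is integrated in arc length (robust through
#' vertical tangents of nodoid branches) and obeys the first integral
#' \eqn{g/\sqrt{1 + g'^2} - H g^2 = B} with \eqn{B = g_0 - H g_0^2}.
#' The family member is classified as sphere, cylinder, catenoid, unduloid
#' or nodoid.
#'
#' @inheritParams hyperboloid_shape
#' @param H_bracket Mean-curvature interval scanned for roots.
#' @param n_scan Scan nodes.
#' @param n_out Output nodes of the returned meridian.
#' @return A `delaunay_solution` with fields `profile` (when the meridian is
#'   single-valued in `z`), `data` (arc-length samples `s`, `z`, `g`,
#'   `psi`), `H`, `B`, `family`, `status` and `residual`.
#' @export
delaunay_solve <- function(g0, R = 1, L = 1.25, H_bracket = c(-5, 5),
                           n_scan = 201, n_out = 201) {
  stopifnot(g0 > 0)
  s_max <- 3 * (L + g0 + R)
  f_scan <- function(H) delaunay_residual(H, g0, R, L, s_max, 1e-7, 1e-9)
  f <- function(H) delaunay_residual(H, g0, R, L, s_max)
  hs <- seq(H_bracket[1], H_bracket[2], length.out = n_scan)
  fs <- vapply(hs, f_scan, numeric(1))
  idx <- which(fs[-1] * fs[-length(fs)] < 0)
  step <- hs[2] - hs[1]
  roots <- vapply(idx, function(i) {
    polish_root(f, hs[i], hs[i + 1], step, H_bracket, 1e-12)
  }, numeric(1))
  roots <- roots[is.finite(roots)]
  roots <- roots[abs(vapply(roots, f, numeric(1))) < 1e-6]
  if (!length(roots)) {
    return(structure(list(status = "no-solution", g0 = g0, R = R, L = L,
                          roots = roots),
                     class = "delaunay_solution"))
  }
  H <- roots[which.min(abs(roots))]
  # final dense integration
  out <- deSolve::lsodar(
    y = c(z = 0, g = g0, psi = 0), times = seq(0, s_max, length.out = 2001),
    func = delaunay_ode_func, parms = list(H = H),
    rootfunc = function(s, y, parms) y[1] - L / 2,
    rtol = 1e-12, atol = 1e-13)
  dat <- tibble::tibble(s = out[, 1], z = out[, 2], g = out[, 3],
                        psi = out[, 4])
  B <- g0 - H * g0^2
  single <- max(abs(dat$psi)) < pi / 2 - 1e-9
  profile <- NULL
  if (single) {
    # build the meridian directly on the integrator's nodes with exact
    # slopes g' = tan(psi) and the curvature relation for g''
    d <- dat[!duplicated(dat$z), ]
    gpp_half <- (cos(d$psi) / d$g - 2 * H) / cos(d$psi)^3
    zg <- c(-rev(d$z[-1]), d$z)
    profile <- profile_curve(
      zg,
      c(rev(d$g[-1]), d$g),
      c(-rev(tan(d$psi)[-1]), tan(d$psi)),
      c(rev(gpp_half[-1]), gpp_half))
  }
  family <- if (abs(H) < 1e-6) "catenoid"
    else if (abs(B) < 1e-6) "sphere"
    else if (abs(g0 - R) < 1e-9 && abs(H - 1 / (2 * g0)) < 1e-6) "cylinder"
    else if (H > 0 && B > 0) "unduloid"
    else "nodoid"
  structure(list(status = "converged", profile = profile, data = dat,
                 H = H, B = B, family = family, g0 = g0, R = R, L = L,
                 residual = f(H), roots = sort(roots),
                 single_valued = single),
            class = "delaunay_solution")
}

#' @export
print.delaunay_solution <- function(x, ...) {
  cat("<delaunay_solution> status:", x$status, "\n")
  if (x$status == "converged") {
    cat("  g0 =", format(x$g0), " H =", format(x$H), " B =", format(x$B),
        " family:", x$family, "\n")
  }
  invisible(x)
}
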