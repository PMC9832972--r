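#' Integration constant of the fiber geodesic equation
#'
#' For a fiber crossing the neck (radius `g0`) at fibril angle `mu0` from the
#' meridian, Clairaut's relation fixes the first-integral constant
#' \eqn{K = 1/(g_0^2 \sin^2\mu_0)}.
#'
#' @param g0 Neck radius (> 0, units of the boundary radius).
#' @param mu0 Fibril angle at the neck in degrees, with \eqn{0 < \mu_0 < 90}.
#' @return The constant `K` (satisfies \eqn{K g_0^2 \ge 1}).
#' @export
k_from_boundary <- function(g0, mu0) {
  stopifnot(g0 > 0)
  if (mu0 >= 90) {
    stop("mu0 must be < 90 degrees: at 90 the fiber degenerates to the ",
         "neck circle (K g0^2 = 1 at the start point)", call. = FALSE)
  }
  if (mu0 <= 0) {
    stop("mu0 = 0 is the meridian-fiber limit (K infinite); ",
         "use torus_segment() for its closed form",
         call. = FALSE)
  }
  1 / (g0^2 * sin(mu0 * pi / 180)^2)
}

#' Right-hand side of the cylindrical fiber equations
#'
#' The governing system for the meridian \eqn{g(z)} and winding angle
#' \eqn{\theta(z)} of a surface stabilized by geodesic fibers of constant
#' normal curvature \eqn{\kappa_T}:
#' \deqn{g'' = \frac{1 + g'^2}{g\,(K g^2 - 1)}\,
#'   \left(1 - K \kappa_T g^3 \sqrt{1 + g'^2}\right), \qquad
#'   \theta' = \frac{1}{g}\sqrt{\frac{1 + g'^2}{K g^2 - 1}}.}
#' The \eqn{\theta'} equation alone is the classical geodesic equation on a
#' surface of revolution; the \eqn{g''} equation enforces constant normal
#' curvature. Valid strictly away from the singular set \eqn{K g^2 = 1}
#' (where the fiber runs tangent to a parallel circle).
#'
#' @param g,g_prime Meridian radius and slope (vectors of equal length).
#' @param K Integration constant, see [k_from_boundary()].
#' @param kappa_T Constant fiber normal curvature (signed; positive for
#'   sphere/barrel shapes, negative for necked shapes).
#' @return A tibble with columns `g_double_prime` and `theta_prime`.
#' @export
fiber_rhs <- function(g, g_prime, K, kappa_T) {
  B <- K * g^2 - 1
  if (any(B <= 0)) {
    stop("singular set reached: K g^2 <= 1 at g = ",
         format(g[which(B <= 0)[1]]), call. = FALSE)
  }
  A <- 1 + g_prime^2
  tibble::tibble(
    g_double_prime = A / (g * B) * (1 - K * kappa_T * g^3 * sqrt(A)),
    theta_prime = sqrt(A / B) / g
  )
}

fiber_ode_func <- function(z, y, parms) {
  B <- parms$K * y[1]^2 - 1
  A <- 1 + y[2]^2
  list(c(y[2],
         A / (y[1] * B) * (1 - parms$K * parms$kappa_T * y[1]^3 * sqrt(A)),
         sqrt(A / B) / y[1]))
}

fiber_ode_root <- function(z, y, parms) {
  c(parms$K * y[1]^2 - 1 - parms$sing_margin,  # tangent to a parallel circle
    y[1] - parms$pinch_g,                      # pinch-off
    parms$max_slope2 - y[2]^2)                 # runaway slope
}

# integrate the half profile on [0, L/2]; returns list(success, data, ...)
integrate_fiber_ode <- function(g0, K, kappa_T, half_L, n_out = 201,
                                rtol = 1e-10, atol = 1e-12) {
  parms <- list(K = K, kappa_T = kappa_T,
                sing_margin = min(1e-7, (K * g0^2 - 1) * 1e-3),
                pinch_g = 1e-6, max_slope2 = 1e6)
  times <- seq(0, half_L, length.out = n_out)
  out <- try(deSolve::lsodar(
    y = c(g = g0, gp = 0, theta = 0), times = times, func = fiber_ode_func,
    parms = parms, rootfunc = fiber_ode_root, rtol = rtol, atol = atol
  ), silent = TRUE)
  if (inherits(out, "try-error")) {
    return(list(success = FALSE, failure_z = 0, failure_mode = "solver",
                g_last = g0, gp_last = 0))
  }
  zend <- out[nrow(out), 1]
  if (zend < half_L - 1e-12) {
    iroot <- which(attr(out, "iroot") == 1)
    mode <- if (length(iroot)) {
      c("singular", "pinch", "steep")[iroot[1]]
    } else "solver"
    return(list(success = FALSE, failure_z = zend, failure_mode = mode,
                g_last = out[nrow(out), 2], gp_last = out[nrow(out), 3]))
  }
  list(success = TRUE,
       data = tibble::tibble(z = out[, 1], g = out[, 2], gp = out[, 3],
                             theta = out[, 4]))
}

#' Integrate a fiber-stabilized half profile and mirror it
#'
#' Integrates the cylindrical system from the neck conditions
#' \eqn{g(0) = g_0,\; g'(0) = 0,\; \theta(0) = 0} up to \eqn{z = L/2} and
#' mirrors the result using the symmetry \eqn{g(-z) = g(z)},
#' \eqn{\theta(-z) = -\theta(z)}. The outer boundary constraint
#' \eqn{g(L/2) = R} is *not* enforced here; see [solve_kappa()].
#'
#' @inheritParams k_from_boundary
#' @param kappa_T Constant fiber normal curvature (signed).
#' @param R Boundary disk radius (defines `pressure` units; default 1).
#' @param L Disk separation; the disks sit at \eqn{z = \pm L/2}.
#' @param n_out Output nodes on the half interval.
#' @param rtol,atol Integration tolerances.
#' @param chirality `"right"` (default, \eqn{\theta' > 0}) or `"left"` for
#'   the mirror-image winding; the model is equally valid for both.
#' @return A `fiber_solution` object; if the integration hits a singularity,
#'   a pinch-off, or a runaway slope before \eqn{L/2}, the object has
#'   `status = "failed"` with the failure position and mode.
#' @export
fiber_profile <- function(g0, mu0, kappa_T, R = 1, L = 1.25, n_out = 201,
                          rtol = 1e-10, atol = 1e-12,
                          chirality = c("right", "left")) {
  chirality <- match.arg(chirality)
  K <- k_from_boundary(g0, mu0)
  half <- integrate_fiber_ode(g0, K, kappa_T, L / 2, n_out, rtol, atol)
  if (!half$success) {
    return(structure(
      list(status = "failed", failure_z = half$failure_z,
           failure_mode = half$failure_mode, g_last = half$g_last,
           gp_last = half$gp_last, g0 = g0, mu0 = mu0, kappa_T = kappa_T,
           K = K, R = R, L = L, chirality = chirality),
      class = "fiber_solution"))
  }
  d <- half$data
  rhs <- fiber_rhs(d$g, d$gp, K, kappa_T)
  sgn <- if (chirality == "right") 1 else -1
  m <- nrow(d)
  full <- tibble::tibble(
    z = c(-rev(d$z[-1]), d$z),
    g = c(rev(d$g[-1]), d$g),
    g_prime = c(-rev(d$gp[-1]), d$gp),
    g_double_prime = c(rev(rhs$g_double_prime[-1]), rhs$g_double_prime),
    theta = sgn * c(-rev(d$theta[-1]), d$theta),
    theta_prime = sgn * c(rev(rhs$theta_prime[-1]), rhs$theta_prime)
  )
  mu0r <- mu0 * pi / 180
  full$alpha <- asin(pmin(1, g0 * sin(mu0r) / full$g))
  profile <- profile_curve(full$z, full$g, full$g_prime, full$g_double_prime)
  gpp0 <- fiber_rhs(g0, 0, K, kappa_T)$g_double_prime
  structure(
    list(status = "ok", data = full, profile = profile, g0 = g0, mu0 = mu0,
         kappa_T = kappa_T, K = K, R = R, L = L, chirality = chirality,
         H_neck = 0.5 * (1 / g0 - gpp0),
         pressure_sign = sign(kappa_T),
         boundary_residual = d$g[m] - R),
    class = "fiber_solution")
}

#' @export
print.fiber_solution <- function(x, ...) {
  if (x$status != "ok") {
    cat("<fiber_solution> FAILED (", x$failure_mode, ") at z = ",
        format(x$failure_z), "\n", sep = "")
    cat("  g0 =", x$g0, " mu0 =", x$mu0, "deg  kappa_T =", x$kappa_T, "\n")
    return(invisible(x))
  }
  cat("<fiber_solution> g0 =", format(x$g0), " mu0 =", format(x$mu0),
      "deg  kappa_T =", format(x$kappa_T), "\n")
  cat("  K =", format(x$K), " H_neck =", format(x$H_neck),
      " g(L/2) - R =", format(x$boundary_residual), "\n")
  invisible(x)
}

#' Reconstruct the 3D fiber path of a solved profile
#'
#' Builds the space curve \eqn{(g\cos(\theta+\theta_0), g\sin(\theta+\theta_0), z)}
#' with analytically propagated first and second derivatives (no finite
#' differences), ready for [curve_frame()] / [colinearity_residual()] checks.
#'
#' @param solution A successful [fiber_profile()] result.
#' @param theta0 Phase offset of the fiber at the neck (radians).
#' @return A `space_curve` tibble (includes exact `xp`,`yp`,`xpp`,`ypp`).
#' @export
fiber_curve <- function(solution, theta0 = 0) {
  stopifnot(inherits(solution, "fiber_solution"), solution$status == "ok")
  d <- solution$data
  K <- solution$K; kap <- solution$kappa_T
  A <- 1 + d$g_prime^2
  B <- K * d$g^2 - 1
  theta_pp <- d$theta_prime * (d$g_prime * d$g_double_prime / A -
                               K * d$g * d$g_prime / B - d$g_prime / d$g)
  th <- d$theta + theta0
  ct <- cos(th); st <- sin(th)
  pts <- tibble::tibble(
    x = d$g * ct, y = d$g * st, z = d$z,
    xp = d$g_prime * ct - d$g * st * d$theta_prime,
    yp = d$g_prime * st + d$g * ct * d$theta_prime,
    xpp = d$g_double_prime * ct - 2 * d$g_prime * st * d$theta_prime -
      d$g * ct * d$theta_prime^2 - d$g * st * theta_pp,
    ypp = d$g_double_prime * st + 2 * d$g_prime * ct * d$theta_prime -
      d$g * st * d$theta_prime^2 + d$g * ct * theta_pp
  )
  curve_frame(pts)
}

#' Family of congruent fibers on a solved surface
#'
#' By rotational symmetry every fiber of the family is the base fiber rotated
#' about the axis: fibers spiral around the axis of revolution in parallel,
#' with Clairaut's relation \eqn{g \sin\alpha = g_0 \sin\mu_0} shared by all.
#'
#' @param solution A successful [fiber_profile()] result.
#' @param n_fibers Number of fibers, phased at \eqn{\theta_0 = 2\pi k/n}.
#' @return A tibble stacking the `space_curve` of each fiber with a leading
#'   `fiber` index column.
#' @export
fiber_family <- function(solution, n_fibers = 1) {
  stopifnot(n_fibers >= 1)
  purrr::map_dfr(seq_len(n_fibers), function(k) {
    fc <- fiber_curve(solution, theta0 = 2 * pi * (k - 1) / n_fibers)
    dplyr::bind_cols(tibble::tibble(fiber = k), fc)
  })
}

cartesian_ode_func <- function(z, y, parms) {
  x <- y[1]; xp <- y[2]; yy <- y[3]; yp <- y[4]
  D <- x^2 * (1 + xp^2) + 2 * x * yy * xp * yp + yy^2 * (1 + yp^2)
  S <- 1 + xp^2 + yp^2
  k <- parms$kappa_eff
  list(c(xp,
         k * (x * (1 + xp^2) + yy * xp * yp) * S / sqrt(D),
         yp,
         k * (x * xp * yp + yy * (1 + yp^2)) * S / sqrt(D)))
}

#' Cartesian form of the fiber equations (independent oracle)
#'
#' Integrates the second-order system for the fiber coordinates
#' \eqn{(x(z), y(z))} directly, without the cylindrical reduction. Under the
#' package sign convention (\eqn{\kappa_T > 0} when the principal normal
#' points toward the interior, so spheres sit at \eqn{\kappa_T > 0}) the
#' curvature enters this system with the opposite sign to the cylindrical
#' one; the mapping is handled internally so both forms accept the same
#' `kappa_T`. The resulting curve must coincide pointwise with
#' [fiber_curve()] of the cylindrical solution — this is the package's main
#' cross-validation route.
#'
#' @inheritParams fiber_profile
#' @return A `space_curve` tibble on \eqn{z \in [0, L/2]}, or a list with
#'   `status = "failed"` on breakdown.
#' @export
fiber_cartesian <- function(g0, mu0, kappa_T, L = 1.25, n_out = 201,
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(g0 > 0, mu0 > 0, mu0 < 90)
  mu0r <- mu0 * pi / 180
  times <- seq(0, L / 2, length.out = n_out)
  out <- try(deSolve::lsoda(
    y = c(x = g0, xp = 0, y = 0, yp = tan(mu0r)), times = times,
    func = cartesian_ode_func, parms = list(kappa_eff = -kappa_T),
    rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < n_out) {
    return(list(status = "failed"))
  }
  pts <- tibble::tibble(x = out[, 2], y = out[, 4], z = out[, 1],
                        xp = out[, 3], yp = out[, 5])
  d2 <- t(apply(out[, -1, drop = FALSE], 1, function(y) {
    unlist(cartesian_ode_func(0, y, list(kappa_eff = -kappa_T)))[c(2, 4)]
  }))
  pts$xpp <- d2[, 1]; pts$ypp <- d2[, 2]
  curve_frame(pts)
}
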