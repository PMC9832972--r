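#' Point on a surface of revolution
#'
#' Maps surface coordinates \eqn{(\theta, z)} to Cartesian space via
#' \eqn{X(\theta, z) = (g(z)\cos\theta, g(z)\sin\theta, z)}.
#'
#' @param profile A [profile_curve()].
#' @param theta Polar angle(s) in radians.
#' @param z Axial coordinate(s), within the profile range.
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
surface_point <- function(profile, theta, z) {
  n <- max(length(theta), length(z))
  theta <- rep_len(theta, n); z <- rep_len(z, n)
  g <- profile_eval(profile, z)
  tibble::tibble(x = g * cos(theta), y = g * sin(theta), z = z)
}

#' Outward unit surface normal
#'
#' For the axisymmetric surface the outward normal (pointing away from the
#' axis of revolution) is
#' \eqn{e_n = (\cos\theta, \sin\theta, -g')/\sqrt{1 + g'^2}}.
#'
#' @inheritParams surface_point
#' @return A tibble with columns `nx`, `ny`, `nz`.
#' @export
surface_normal <- function(profile, theta, z) {
  n <- max(length(theta), length(z))
  theta <- rep_len(theta, n); z <- rep_len(z, n)
  gp <- profile_eval(profile, z, deriv = 1L)
  s <- sqrt(1 + gp^2)
  if (any(!is.finite(s))) stop("degenerate profile: non-finite slope",
                               call. = FALSE)
  tibble::tibble(nx = cos(theta) / s, ny = sin(theta) / s, nz = -gp / s)
}

#' Orthonormal surface frame and principal curvatures
#'
#' Returns the right-handed triad \eqn{e_1 \times e_2 = e_3} with
#' `e1` the circumferential direction, `e2` the meridian direction and
#' `e3` the outward normal, together with the principal curvatures
#' `k1` (circumferential, \eqn{1/(g\sqrt{1+g'^2})}) and `k2` (meridional,
#' \eqn{-g''/(1+g'^2)^{3/2}}). With this orientation a sphere of radius
#' \eqn{\rho} has \eqn{k_1 = k_2 = 1/\rho} and mean curvature \eqn{+1/\rho}.
#'
#' @inheritParams surface_point
#' @return A tibble with the frame components and principal curvatures.
#' @export
surface_frame <- function(profile, theta, z) {
  n <- max(length(theta), length(z))
  theta <- rep_len(theta, n); z <- rep_len(z, n)
  g <- profile_eval(profile, z)
  gp <- profile_eval(profile, z, deriv = 1L)
  gpp <- profile_eval(profile, z, deriv = 2L)
  s <- sqrt(1 + gp^2)
  tibble::tibble(
    theta = theta, z = z,
    e1x = -sin(theta), e1y = cos(theta), e1z = 0,
    e2x = gp * cos(theta) / s, e2y = gp * sin(theta) / s, e2z = 1 / s,
    e3x = cos(theta) / s, e3y = sin(theta) / s, e3z = -gp / s,
    k1 = 1 / (g * s), k2 = -gpp / s^3
  )
}

#' Mean curvature of a surface of revolution
#'
#' \eqn{H(z) = \frac{1}{2}\left(\frac{1}{g\sqrt{1+g'^2}} -
#' \frac{g''}{(1+g'^2)^{3/2}}\right)}, which reduces to
#' \eqn{(1/g - g'')/2} at a neck (\eqn{g' = 0}). Sign convention: a sphere of
#' radius \eqn{\rho} has \eqn{H = +1/\rho}, a catenoid \eqn{H = 0}.
#'
#' @param profile A [profile_curve()].
#' @param z Axial coordinate(s).
#' @return Numeric vector of mean curvatures.
#' @export
mean_curvature <- function(profile, z) {
  g <- profile_eval(profile, z)
  gp <- profile_eval(profile, z, deriv = 1L)
  gpp <- profile_eval(profile, z, deriv = 2L)
  s2 <- 1 + gp^2
  0.5 * (1 / (g * sqrt(s2)) - gpp / s2^1.5)
}

#' Frenet frame and curvature of a space curve
#'
#' Computes the unit tangent, the principal normal \eqn{e_p} (pointing toward
#' the local centre of curvature) and the pointwise curvature
#' \eqn{\kappa = |X' \times X''| / |X'|^3} of an ordered set of 3D points.
#' With the axial coordinate as parameter (the default) the implemented
#' component formulas are exactly the coordinate expressions for curves
#' \eqn{(x(z), y(z), z)}; a general parameter column `t` is also accepted so
#' that planar circles and other curves with vertical tangents can be framed.
#'
#' Straight segments have no osculating plane: points where
#' \eqn{\kappa < } `tol_straight` keep `kappa = 0` but are flagged
#' `frame_defined = FALSE` and carry `NA` principal normals.
#'
#' @param points A data frame with columns `x`, `y`, `z` and optionally a
#'   parameter column `t` (otherwise `z` is the parameter and must be
#'   strictly monotone). Optional columns `xp`, `yp`, `xpp`, `ypp` supply
#'   exact derivatives with respect to `z` and suppress spline
#'   differentiation.
#' @param tol_straight Curvature below which the frame is declared
#'   undefined (well below any physical fiber curvature, above the noise of
#'   spline differentiation of straight rulings).
#' @return A tibble of class `space_curve` with unit tangent (`tx`,`ty`,`tz`),
#'   principal normal (`px`,`py`,`pz`), `kappa` and `frame_defined`.
#' @export
curve_frame <- function(points, tol_straight = 1e-9) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  if (all(c("xp", "yp", "zp", "xpp", "ypp", "zpp") %in% names(points))) {
    # fully analytic derivatives with respect to an arbitrary parameter
    d1 <- cbind(points$xp, points$yp, points$zp)
    d2 <- cbind(points$xpp, points$ypp, points$zpp)
  } else if (all(c("xp", "yp", "xpp", "ypp") %in% names(points))) {
    d1 <- cbind(points$xp, points$yp, rep(1, nrow(points)))
    d2 <- cbind(points$xpp, points$ypp, rep(0, nrow(points)))
  } else {
    par <- if ("t" %in% names(points)) points$t else points$z
    if (any(diff(par) <= 0)) {
      stop("curve parameter must be strictly increasing ",
           "(supply a `t` column for curves not monotone in z)",
           call. = FALSE)
    }
    sx <- stats::splinefun(par, points$x, method = "natural")
    sy <- stats::splinefun(par, points$y, method = "natural")
    sz <- stats::splinefun(par, points$z, method = "natural")
    d1 <- cbind(sx(par, 1L), sy(par, 1L), sz(par, 1L))
    d2 <- cbind(sx(par, 2L), sy(par, 2L), sz(par, 2L))
  }
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  n1 <- sqrt(rowSums(d1^2))
  ncr <- sqrt(rowSums(cr^2))
  kappa <- ncr / n1^3
  tangent <- d1 / n1
  # e_p = ((X' x X'') x X') / (|X' x X''| |X'|); for z-parameterized curves
  # this is the printed coordinate form of the fiber principal normal.
  ep <- cbind(cr[, 2] * d1[, 3] - cr[, 3] * d1[, 2],
              cr[, 3] * d1[, 1] - cr[, 1] * d1[, 3],
              cr[, 1] * d1[, 2] - cr[, 2] * d1[, 1])
  den <- ncr * n1
  defined <- kappa >= tol_straight
  ep <- ep / ifelse(den > 0, den, NA_real_)
  ep[!defined, ] <- NA_real_
  kappa[!defined] <- 0
  out <- tibble::tibble(
    x = points$x, y = points$y, z = points$z,
    tx = tangent[, 1], ty = tangent[, 2], tz = tangent[, 3],
    px = ep[, 1], py = ep[, 2], pz = ep[, 3],
    kappa = kappa, frame_defined = defined
  )
  class(out) <- c("space_curve", class(out))
  out
}

#' Colinearity of a curve's principal normal with the surface normal
#'
#' An equilibrium fiber must satisfy \eqn{e_p \times e_n \equiv 0}: the
#' resultant contractile force (along the principal normal) must be able to
#' balance the pressure (along the surface normal). This returns
#' \eqn{|e_p \times e_n|} per point, which vanishes exactly on geodesics.
#' The signed normal component \eqn{e_p \cdot e_n} is also returned; the
#' package's fiber curvature convention is
#' \eqn{\kappa_T = -\kappa\, (e_p \cdot e_n)} (positive when the principal
#' normal points into the tissue interior, as on a sphere).
#'
#' @param curve A [curve_frame()] result (or points accepted by it).
#' @param profile The [profile_curve()] on which the curve is supposed to lie.
#' @param tol_on_surface Maximum allowed distance from the surface.
#' @return The curve tibble with extra columns `residual`,
#'   `normal_component` and `kappa_signed`.
#' @export
colinearity_residual <- function(curve, profile, tol_on_surface = 1e-8) {
  if (!inherits(curve, "space_curve")) curve <- curve_frame(curve)
  r <- sqrt(curve$x^2 + curve$y^2)
  dist <- abs(r - profile_eval(profile, curve$z))
  if (max(dist) > tol_on_surface) {
    stop("curve does not lie on the surface: max |r - g(z)| = ",
         format(max(dist)), call. = FALSE)
  }
  en <- surface_normal(profile, atan2(curve$y, curve$x), curve$z)
  cx <- curve$py * en$nz - curve$pz * en$ny
  cy <- curve$pz * en$nx - curve$px * en$nz
  cz <- curve$px * en$ny - curve$py * en$nx
  dot <- curve$px * en$nx + curve$py * en$ny + curve$pz * en$nz
  out <- curve
  out$residual <- sqrt(cx^2 + cy^2 + cz^2)
  out$normal_component <- dot
  out$kappa_signed <- -out$kappa * sign(round(dot, 6))
  out
}
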