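#' Meridian profile of a surface of revolution
#'
#' A `profile_curve` stores the shape function \eqn{g(z)} of an axisymmetric
#' surface \eqn{X(\theta, z) = (g(z)\cos\theta,\; g(z)\sin\theta,\; z)} on a
#' strictly increasing axial grid, together with its first and second
#' derivatives with respect to \eqn{z}. Between grid nodes the profile is
#' evaluated by piecewise-cubic Hermite interpolation that honours the stored
#' derivatives; analytic profiles built by the reference-shape constructors
#' carry exact closures instead and are evaluated from those.
#'
#' @param z Strictly increasing numeric vector of axial coordinates
#'   (dimensionless, in units of the boundary radius).
#' @param g Meridian radius at each `z`; must be positive.
#' @param g_prime,g_double_prime Optional derivatives of `g` with respect to
#'   `z` at the grid nodes. When omitted they are estimated with a natural
#'   cubic spline through `(z, g)`.
#' @param funs Optional list of exact closures `g`, `g_prime`,
#'   `g_double_prime`, each mapping `z` to a numeric vector. When present
#'   they take precedence over interpolation.
#' @param smooth Logical; `FALSE` marks profiles with derivative jumps
#'   (e.g. stacked spherical segments), which are limit cases.
#'
#' @return A tibble of class `profile_curve` with columns `z`, `g`,
#'   `g_prime`, `g_double_prime`.
#' @examples
#' pr <- profile_curve(seq(-0.5, 0.5, length.out = 51), rep(1, 51),
#'                     rep(0, 51), rep(0, 51))
#' mean_curvature(pr, 0) # cylinder of unit radius: H = 1/2
#' @export
profile_curve <- function(z, g, g_prime = NULL, g_double_prime = NULL,
                          funs = NULL, smooth = TRUE) {
  stopifnot(is.numeric(z), is.numeric(g), length(z) == length(g),
            length(z) >= 2)
  if (any(diff(z) <= 0)) {
    stop("`z` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(g)) || any(g <= 0)) {
    stop("`g` must be positive and finite everywhere", call. = FALSE)
  }
  if (is.null(g_prime)) {
    sf <- stats::splinefun(z, g, method = "natural")
    g_prime <- sf(z, deriv = 1L)
    if (is.null(g_double_prime)) g_double_prime <- sf(z, deriv = 2L)
  }
  if (is.null(g_double_prime)) {
    # derivative of the Hermite interpolant of g' is the best grid estimate
    sf1 <- stats::splinefun(z, g_prime, method = "natural")
    g_double_prime <- sf1(z, deriv = 1L)
  }
  out <- tibble::tibble(z = as.numeric(z), g = as.numeric(g),
                        g_prime = as.numeric(g_prime),
                        g_double_prime = as.numeric(g_double_prime))
  class(out) <- c("profile_curve", class(out))
  attr(out, "funs") <- funs
  attr(out, "smooth") <- isTRUE(smooth)
  out
}

#' Build a profile from analytic shape functions
#'
#' @param g_fun Function of `z` returning the meridian radius.
#' @param z_range Length-2 numeric, the axial extent.
#' @param g_prime_fun,g_double_prime_fun Optional exact derivatives; when
#'   omitted they are computed by central differences of `g_fun`.
#' @param n Number of grid nodes.
#' @inheritParams profile_curve
#' @return A `profile_curve`.
#' @export
profile_from_function <- function(g_fun, z_range, g_prime_fun = NULL,
                                  g_double_prime_fun = NULL, n = 201,
                                  smooth = TRUE) {
  z <- seq(z_range[1], z_range[2], length.out = n)
  h <- 1e-6 * max(1, diff(z_range))
  if (is.null(g_prime_fun)) {
    g_prime_fun <- function(zz) (g_fun(zz + h) - g_fun(zz - h)) / (2 * h)
  }
  if (is.null(g_double_prime_fun)) {
    g_double_prime_fun <- function(zz) {
      (g_fun(zz + h) - 2 * g_fun(zz) + g_fun(zz - h)) / h^2
    }
  }
  profile_curve(z, g_fun(z), g_prime_fun(z), g_double_prime_fun(z),
                funs = list(g = g_fun, g_prime = g_prime_fun,
                            g_double_prime = g_double_prime_fun),
                smooth = smooth)
}

# piecewise-cubic Hermite evaluation honouring supplied slopes
hermite_eval <- function(x, y, m, xout, deriv = 0L) {
  i <- findInterval(xout, x, rightmost.closed = TRUE, all.inside = TRUE)
  h <- x[i + 1L] - x[i]
  t <- (xout - x[i]) / h
  y0 <- y[i]; y1 <- y[i + 1L]; m0 <- m[i]; m1 <- m[i + 1L]
  if (deriv == 0L) {
    (2 * t^3 - 3 * t^2 + 1) * y0 + (t^3 - 2 * t^2 + t) * h * m0 +
      (-2 * t^3 + 3 * t^2) * y1 + (t^3 - t^2) * h * m1
  } else if (deriv == 1L) {
    ((6 * t^2 - 6 * t) * (y0 - y1)) / h + (3 * t^2 - 4 * t + 1) * m0 +
      (3 * t^2 - 2 * t) * m1
  } else {
    ((12 * t - 6) * (y0 - y1)) / h^2 + (6 * t - 4) * m0 / h +
      (6 * t - 2) * m1 / h
  }
}

#' Evaluate a profile (and its derivatives) at arbitrary z
#'
#' @param profile A [profile_curve()].
#' @param z Numeric vector of axial coordinates within the profile range.
#' @param deriv 0, 1 or 2: evaluate \eqn{g}, \eqn{g'} or \eqn{g''}.
#' @return Numeric vector.
#' @export
profile_eval <- function(profile, z, deriv = 0L) {
  rng <- range(profile$z)
  if (any(z < rng[1] - 1e-12) || any(z > rng[2] + 1e-12)) {
    stop("z out of the profile range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  z <- pmin(pmax(z, rng[1]), rng[2])
  funs <- attr(profile, "funs")
  if (!is.null(funs)) {
    f <- switch(as.character(deriv), "0" = funs$g, "1" = funs$g_prime,
                "2" = funs$g_double_prime)
    if (!is.null(f)) return(f(z))
  }
  switch(as.character(deriv),
    "0" = hermite_eval(profile$z, profile$g, profile$g_prime, z),
    "1" = hermite_eval(profile$z, profile$g_prime, profile$g_double_prime, z),
    "2" = hermite_eval(profile$z, profile$g_prime, profile$g_double_prime, z,
                       deriv = 1L))
}

#' Check internal consistency of a profile's derivative columns
#'
#' Compares the stored `g_prime` against centred finite differences of the
#' interpolated `g`. Profiles flagged as non-smooth (stacked segments) are
#' checked away from their joints.
#'
#' @param profile A [profile_curve()].
#' @param tol Allowed absolute discrepancy.
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_profile <- function(profile, tol = 1e-6) {
  rng <- range(profile$z)
  h <- diff(rng) * 1e-5
  zi <- profile$z[profile$z > rng[1] + 2 * h & profile$z < rng[2] - 2 * h]
  joints <- attr(profile, "joints")
  if (!is.null(joints)) {
    keep <- vapply(zi, function(z) all(abs(z - joints) > 10 * h), logical(1))
    zi <- zi[keep]
  }
  fd <- (profile_eval(profile, zi + h) - profile_eval(profile, zi - h)) / (2 * h)
  err <- max(abs(fd - profile_eval(profile, zi, deriv = 1L)))
  if (err > tol) {
    stop("profile derivatives inconsistent with g: max error ",
         format(err), call. = FALSE)
  }
  invisible(TRUE)
}
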