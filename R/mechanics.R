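# quantity parsing: numbers are taken as SI; strings carry an explicit unit
# suffix and are converted. Passing a unit of the wrong dimension errors, so
# Pa/kPa/um cannot be mixed silently.
unit_table <- list(
  pressure = c("Pa" = 1, "kPa" = 1e3, "MPa" = 1e6),
  length   = c("m" = 1, "mm" = 1e-3, "um" = 1e-6, "nm" = 1e-9),
  tension  = c("N/m" = 1, "mN/m" = 1e-3)
)

#' Parse a physical quantity with an explicit unit suffix
#'
#' Numeric input is interpreted as SI (`Pa`, `m`, `N/m`); character input
#' such as `"2kPa"`, `"10um"` or `"20mN/m"` is converted. A unit of the
#' wrong physical dimension is an error — the package's guard against mixing
#' scales without conversion.
#'
#' @param x Numeric, or a character scalar/vector like `"2kPa"`.
#' @param dimension `"pressure"`, `"length"` or `"tension"`.
#' @return Numeric value(s) in SI units.
#' @export
parse_quantity <- function(x, dimension = c("pressure", "length", "tension")) {
  dimension <- match.arg(dimension)
  if (is.numeric(x)) return(x)
  tab <- unit_table[[dimension]]
  vapply(x, function(s) {
    s <- gsub("\\s+", "", s)
    m <- regmatches(s, regexec("^([-+0-9.eE]+)(.*)$", s))[[1]]
    if (length(m) != 3 || m[3] == "") {
      stop("cannot parse quantity '", s, "': need e.g. '2kPa'",
           call. = FALSE)
    }
    if (!m[3] %in% names(tab)) {
      stop("unit '", m[3], "' is not a ", dimension, " unit (expected one ",
           "of: ", paste(names(tab), collapse = ", "), ")", call. = FALSE)
    }
    as.numeric(m[2]) * tab[[m[3]]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classical Young–Laplace pressure
#'
#' \eqn{p = -\gamma_s (1/R_1 + 1/R_2) = -2\gamma_s H} for an isotropic
#' surface stress \eqn{\gamma_s}. The package-wide sign convention defines
#' `p` as interior minus exterior pressure with tension on a convex
#' (sphere-like, \eqn{H > 0}) surface compressing the interior; the classical
#' relation is reported with its printed sign, i.e. the negative of the
#' compressive interpretation.
#'
#' @param gamma_s Isotropic surface stress (N/m; or e.g. `"20mN/m"`).
#' @param R1,R2 Signed principal curvature radii (m; or e.g. `"1mm"`).
#' @return Pressure difference in Pa.
#' @export
young_laplace <- function(gamma_s, R1, R2) {
  gamma_s <- parse_quantity(gamma_s, "tension")
  R1 <- parse_quantity(R1, "length"); R2 <- parse_quantity(R2, "length")
  if (any(R1 == 0) || any(R2 == 0)) {
    stop("principal radii must be nonzero", call. = FALSE)
  }
  -gamma_s * (1 / R1 + 1 / R2)
}

#' Axisymmetric membrane equilibrium pressure
#'
#' \eqn{p = N_1/R_1 + N_2/R_2} with tensile membrane forces per length
#' \eqn{N_1, N_2} along the principal curvature lines. With isotropic forces
#' \eqn{N_1 = N_2 = \gamma_s} this is the magnitude of the Young–Laplace
#' pressure (opposite orientation convention for `p`); with the force
#' transverse to the fiber equal to zero it reduces exactly to
#' [fiber_pressure()].
#'
#' @param N1,N2 Membrane forces per length (N/m).
#' @param R1,R2 Signed principal curvature radii (m).
#' @return Pressure difference in Pa.
#' @export
membrane_pressure <- function(N1, N2, R1, R2) {
  N1 <- parse_quantity(N1, "tension"); N2 <- parse_quantity(N2, "tension")
  R1 <- parse_quantity(R1, "length"); R2 <- parse_quantity(R2, "length")
  if (any(R1 == 0) || any(R2 == 0)) {
    stop("principal radii must be nonzero", call. = FALSE)
  }
  N1 / R1 + N2 / R2
}

#' Tissue pressure generated by contractile surface fibers
#'
#' \eqn{p = d\,\sigma_T / R_T}: a contractile layer of thickness `d` under
#' fiber stress \eqn{\sigma_T}, wound along geodesics of curvature radius
#' \eqn{R_T}, pressurizes the interior in proportion to the fiber curvature.
#' The sign of `p` follows the sign of \eqn{1/R_T} (positive for
#' sphere/barrel shapes, negative for necks).
#'
#' @param d Contractile layer thickness (m; or e.g. `"10um"`).
#' @param sigma_T Fiber stress (Pa; or e.g. `"2kPa"`).
#' @param R_T Signed fiber curvature radius (m; or e.g. `"1mm"`).
#' @return Pressure in Pa.
#' @export
fiber_pressure <- function(d, sigma_T, R_T) {
  d <- parse_quantity(d, "length")
  sigma_T <- parse_quantity(sigma_T, "pressure")
  R_T <- parse_quantity(R_T, "length")
  stopifnot(all(d > 0))
  if (any(R_T == 0)) stop("R_T must be nonzero", call. = FALSE)
  d * sigma_T / R_T
}

#' Surface-tension equivalent of a contractile layer
#'
#' Converts a fiber stress acting through a layer thickness into an
#' effective surface tension \eqn{\sigma_T \cdot d}, reported in mN/m.
#' Myofibroblast-scale stresses of 2–5 kPa over the top 10 um of a tissue
#' give 20–50 mN/m, one to two orders above typical isotropic tissue
#' surface tensions.
#'
#' @param sigma_T Fiber stress (Pa; or e.g. `"2kPa"`).
#' @param d Layer thickness (m; or e.g. `"10um"`).
#' @return Effective tension in mN/m.
#' @export
effective_tension <- function(sigma_T, d) {
  sigma_T <- parse_quantity(sigma_T, "pressure")
  d <- parse_quantity(d, "length")
  stopifnot(all(sigma_T >= 0), all(d > 0))
  sigma_T * d * 1e3
}
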