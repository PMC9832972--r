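#' Iso-fibril-angle parameter sweep
#'
#' Traces the relationship between neck radius \eqn{g_0}, fiber curvature
#' \eqn{\kappa_T} and neck mean curvature \eqn{H_{neck}} at fixed fibril
#' angles — the grey curves of the phase diagrams. The mean curvature is not
#' constant over these surfaces; \eqn{H_{neck}} is evaluated at the neck from
#' the ODE right-hand side (not finite differences).
#'
#' Inputs are sorted and de-duplicated internally, so the result is
#' independent of the order of the supplied grids. Along each angle the
#' branch is continued in \eqn{g_0} with a warm-started curvature bracket
#' (full bracket scan as fallback), which keeps the sweep fast without
#' changing which branch is found.
#'
#' @param mu0 Fibril angles at the neck, degrees (0 allowed: torus branch).
#' @param g0 Neck radii to visit.
#' @param R,L Boundary geometry.
#' @param bracket,n_scan Passed to [solve_kappa()] for cold starts.
#' @return A tibble of class `fibershape_sweep` with columns `mu0`, `g0`,
#'   `kappa_T`, `H_neck`, `status`, `pressure_sign`, ordered by `mu0`, `g0`.
#' @export
sweep_iso_mu0 <- function(mu0 = c(0, 10, 20, 30, 35, 40, 50, 58, 70),
                          g0 = seq(0.05, 1.17, by = 0.01),
                          R = 1, L = 1.25, bracket = c(-20, 20), n_scan = 97) {
  mu0 <- sort(unique(mu0)); g0 <- sort(unique(g0))
  rows <- purrr::map_dfr(mu0, function(m) {
    prev_kappa <- NA_real_
    purrr::map_dfr(g0, function(g) {
      res <- NULL
      if (is.finite(prev_kappa)) {
        for (w in c(0.15, 0.6)) {
          cand <- try(solve_kappa(g, m, R, L,
                                  bracket = prev_kappa + c(-w, w),
                                  n_scan = 17), silent = TRUE)
          if (!inherits(cand, "try-error") &&
              cand$status == "converged") { res <- cand; break }
        }
      }
      if (is.null(res) || res$status != "converged") {
        res <- solve_kappa(g, m, R, L, bracket = bracket, n_scan = n_scan)
      }
      if (res$status == "converged") {
        prev_kappa <<- res$kappa_T
        tibble::tibble(mu0 = m, g0 = g, kappa_T = res$kappa_T,
                       H_neck = res$solution$H_neck, status = "converged",
                       pressure_sign = sign(res$kappa_T))
      } else {
        tibble::tibble(mu0 = m, g0 = g, kappa_T = NA_real_,
                       H_neck = NA_real_, status = "no-solution",
                       pressure_sign = NA_real_)
      }
    })
  })
  class(rows) <- c("fibershape_sweep", class(rows))
  attr(rows, "R") <- R; attr(rows, "L") <- L
  rows
}

# mean curvature at the neck of the zero-fiber-curvature (hyperboloid) locus;
# its analytic continuation above g0 = R passes through the sphere landmark.
hyperboloid_H_neck <- function(g0, R = 1, L = 1.25) {
  m <- (R^2 - g0^2) / (L / 2)^2
  (1 - m) / (2 * g0)
}

#' Pressure-sign classification of equilibrium records
#'
#' Under the fiber model the tissue pressure is \eqn{p = d\,\sigma_T/R_T},
#' so its sign is the sign of \eqn{\kappa_T}; under the isotropic
#' (Young–Laplace) model it is \eqn{-2\gamma_s H} acting outward, positive
#' for \eqn{H_{neck} > 0}. Accepts a sweep tibble (or any tibble with the
#' needed columns) and returns it with a `pressure_sign` column.
#'
#' @param records A tibble with `kappa_T` (fiber model) or `H_neck`
#'   (isotropic model) columns; non-converged rows give `NA`.
#' @param model `"fiber"` or `"isotropic"`.
#' @param zero_tol Magnitudes below this count as zero pressure.
#' @return `records` with `pressure_sign` of -1, 0 or +1.
#' @export
pressure_region <- function(records, model = c("fiber", "isotropic"),
                            zero_tol = 1e-9) {
  model <- match.arg(model)
  v <- if (model == "fiber") records$kappa_T else records$H_neck
  s <- sign(v)
  s[abs(v) < zero_tol] <- 0
  records$pressure_sign <- s
  records
}

#' Neck radius of vanishing tissue pressure
#'
#' The isotropic model changes pressure sign at the catenoid (zero mean
#' curvature); the fiber model at the hyperboloid (zero fiber curvature)
#' whose rulings cross the waist at the requested fibril angle. For the
#' reference geometry (R = 1, L = 1.25) these necks are about 0.7 and —
#' at a 35 degree fibril angle — about 0.9.
#'
#' @param model `"isotropic"` or `"fiber"`.
#' @param mu0 Fibril angle (degrees) for the fiber model; 0 gives the
#'   cylinder (`g0 = R`).
#' @param R,L Boundary geometry.
#' @param method `"analytic"` (closed form) or `"sweep"` (locates the
#'   \eqn{\kappa_T = 0} crossing of the shooting family numerically).
#' @return The neck radius `g0` at zero pressure.
#' @export
zero_pressure_neck <- function(model = c("isotropic", "fiber"), mu0 = NULL,
                               R = 1, L = 1.25,
                               method = c("analytic", "sweep")) {
  model <- match.arg(model); method <- match.arg(method)
  if (model == "isotropic") {
    if (method == "analytic") return(catenoid_neck(R, L)$c)
    d <- function(g) {
      sol <- delaunay_solve(g, R, L)
      if (sol$status != "converged") sol <- delaunay_solve(g, R, L,
                                                           n_scan = 801)
      if (sol$status != "converged") {
        stop("Delaunay solve failed at g0 = ", g, call. = FALSE)
      }
      sol$H
    }
    return(stats::uniroot(d, c(0.5 * R, 0.95 * R), tol = 1e-9)$root)
  }
  stopifnot(!is.null(mu0), mu0 >= 0, mu0 < 90)
  if (mu0 == 0) return(R)
  m <- tan(mu0 * pi / 180)^2
  g0sq <- R^2 - m * (L / 2)^2
  if (method == "analytic") {
    if (g0sq <= 0) stop("no zero-pressure neck: fibril angle too steep for ",
                        "a hyperboloid through the boundary", call. = FALSE)
    return(sqrt(g0sq))
  }
  f <- function(g) {
    r <- solve_kappa(g, mu0, R, L, bracket = c(-0.75, 0.75), n_scan = 49)
    if (r$status != "converged") r <- solve_kappa(g, mu0, R, L)
    if (r$status != "converged") {
      stop("shooting failed at g0 = ", g, call. = FALSE)
    }
    r$kappa_T
  }
  g_guess <- sqrt(max(g0sq, 1e-4))
  stats::uniroot(f, c(max(0.1, g_guess - 0.1), min(R, g_guess + 0.1)),
                 tol = 1e-8)$root
}

#' Profile deviation between fiber-stabilized and Delaunay shapes
#'
#' For matched neck radii, solves both boundary-value problems and reports
#' the sup-norm meridian deviation and the neck mean-curvature difference —
#' the quantitative version of "essentially indistinguishable in a typical
#' tissue culture experiment".
#'
#' @param mu0 Fibril angle (degrees) of the fiber model.
#' @param g0 Neck radii to compare at.
#' @param R,L Boundary geometry.
#' @param n_z Comparison grid size over \eqn{[-L/2, L/2]}.
#' @return A tibble with `g0`, `sup_dev` (max over z of
#'   \eqn{|g_{fiber} - g_{Delaunay}|}), `dH_neck`, and a `status` column
#'   recording solvability of each side.
#' @export
delaunay_proximity <- function(mu0, g0, R = 1, L = 1.25, n_z = 201) {
  zg <- seq(-L / 2, L / 2, length.out = n_z)
  purrr::map_dfr(g0, function(g) {
    fib <- solve_kappa(g, mu0, R, L)
    del <- delaunay_solve(g, R, L)
    if (fib$status != "converged" || del$status != "converged" ||
        is.null(del$profile)) {
      return(tibble::tibble(g0 = g, sup_dev = NA_real_, dH_neck = NA_real_,
                            status = paste0("fiber:", fib$status,
                                            "/delaunay:", del$status)))
    }
    dev <- max(abs(profile_eval(fib$solution$profile, zg) -
                   profile_eval(del$profile, zg)))
    tibble::tibble(g0 = g, sup_dev = dev,
                   dH_neck = fib$solution$H_neck - del$H,
                   status = "converged")
  })
}

#' Classify experimental points by predicted pressure sign
#'
#' Annotates measured \eqn{(H_{neck}, g_0)} pairs (for example from tissue
#' culture experiments) with the pressure sign predicted by each model: the
#' isotropic model changes sign across the vertical \eqn{H = 0} line, the
#' fiber model across the hyperboloid (zero fiber curvature) curve.
#'
#' @param points A data frame with columns `H_neck` and `g0`, or the path of
#'   a CSV file with those columns.
#' @param R,L Boundary geometry.
#' @return A tibble with the input columns plus `isotropic_sign` and
#'   `fiber_sign`.
#' @export
overlay_experiment <- function(points, R = 1, L = 1.25) {
  if (is.character(points)) {
    points <- readr::read_csv(points, show_col_types = FALSE)
  }
  points <- tibble::as_tibble(points)
  if (nrow(points) == 0) {
    return(tibble::tibble(H_neck = numeric(0), g0 = numeric(0),
                          isotropic_sign = numeric(0),
                          fiber_sign = numeric(0)))
  }
  if (!all(c("H_neck", "g0") %in% names(points))) {
    stop("points need columns `H_neck` and `g0`", call. = FALSE)
  }
  points$isotropic_sign <- sign(points$H_neck)
  # below the hyperboloid curve in the (H_neck, g0) plane <=>
  # H_neck above the curve's value at that g0 <=> negative fiber pressure.
  # The zero-curvature locus only exists for necked shapes; every barrel
  # (g0 >= R) is stabilized by positively curved fibers.
  points$fiber_sign <- ifelse(
    points$g0 >= R, 1,
    sign(hyperboloid_H_neck(points$g0, R, L) - points$H_neck))
  points
}
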