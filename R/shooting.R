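# Signed shooting residual in kappa_T: g(L/2) - R where the integration
# reaches the boundary, and a signed distance-to-failure penalty where it
# does not, so that brackets spanning failure regions still change sign.
kappa_residual <- function(kappa_T, g0, K, R, L, rtol = 1e-10,
                           atol = 1e-12) {
  half <- integrate_fiber_ode(g0, K, kappa_T, L / 2, n_out = 2,
                              rtol = rtol, atol = atol)
  if (half$success) {
    return(half$data$g[nrow(half$data)] - R)
  }
  pen <- 1 + (L / 2 - half$failure_z) / (L / 2)
  low <- switch(half$failure_mode,
                pinch = TRUE,
                singular = TRUE,
                steep = half$gp_last < 0,
                TRUE)
  if (low) -pen else pen
}

# Brent polish on [lo, hi]; the interval comes from a coarsely integrated
# scan, so when the accurate residual disagrees in sign at an endpoint the
# interval is widened by one scan step before giving up.
polish_root <- function(f, lo, hi, step, limits, tol) {
  for (pad in c(0, step)) {
    a <- max(limits[1], lo - pad); b <- min(limits[2], hi + pad)
    r <- try(stats::uniroot(f, lower = a, upper = b, tol = tol),
             silent = TRUE)
    if (!inherits(r, "try-error")) return(r$root)
  }
  NA_real_
}

new_shooting_result <- function(parameter, value, solution, residual, bracket,
                                status, roots) {
  structure(list(parameter = parameter, value = value, solution = solution,
                 kappa_T = if (parameter == "kappa_T") value
                           else solution$kappa_T,
                 residual = residual, bracket = bracket, status = status,
                 roots = roots),
            class = "shooting_result")
}

#' @export
print.shooting_result <- function(x, ...) {
  cat("<shooting_result> status:", x$status, "\n")
  if (x$status == "converged") {
    cat("  ", x$parameter, "=", format(x$value),
        "  |g(L/2) - R| =", format(abs(x$residual)), "\n")
    if (nrow(x$roots) > 1) {
      cat("  ", nrow(x$roots), "roots found; smallest |kappa_T| is primary\n")
    }
  }
  invisible(x)
}

#' Solve the outer boundary condition by shooting on the fiber curvature
#'
#' Fixes the neck radius `g0` and fibril angle `mu0` and finds the constant
#' fiber curvature(s) \eqn{\kappa_T} for which the integrated profile meets
#' the boundary circles, \eqn{g(\pm L/2) = R}. The bracket is scanned on a
#' uniform grid for sign changes of the (penalty-extended) residual and each
#' change is polished by Brent's method; all roots are reported and the one
#' of smallest \eqn{|\kappa_T|} is returned as primary.
#'
#' The meridian-fiber limit `mu0 = 0` is dispatched to its closed forms: the
#' cylinder when `g0 = R` and the torus-segment arc otherwise.
#'
#' @inheritParams fiber_profile
#' @param bracket Curvature interval searched.
#' @param n_scan Number of scan nodes across the bracket.
#' @param tol Root tolerance on \eqn{\kappa_T}.
#' @return A `shooting_result` with fields `solution` (a
#'   [fiber_profile()] object), `kappa_T`, `residual`, `bracket`, `status`
#'   (`"converged"` or `"no-sign-change"`) and a `roots` tibble.
#' @export
solve_kappa <- function(g0, mu0, R = 1, L = 1.25, bracket = c(-20, 20),
                        n_scan = 97, tol = 1e-10) {
  stopifnot(g0 > 0, mu0 >= 0, mu0 < 90)
  if (mu0 == 0) {
    if (abs(g0 - R) < 1e-12) {
      sol <- cylinder_solution(R, L)
      return(new_shooting_result("kappa_T", 0, sol, 0, bracket, "converged",
                                 tibble::tibble(kappa_T = 0, residual = 0)))
    }
    ts <- torus_segment(g0, R, L)
    sol <- structure(list(status = "ok", data = NULL, profile = ts$profile,
                          g0 = g0, mu0 = 0, kappa_T = ts$kappa_T, K = Inf,
                          R = R, L = L, chirality = "right",
                          H_neck = 0.5 * (1 / g0 + ts$kappa_T),
                          pressure_sign = sign(ts$kappa_T),
                          boundary_residual = 0),
                     class = "fiber_solution")
    return(new_shooting_result("kappa_T", ts$kappa_T, sol, 0, bracket,
                               "converged",
                               tibble::tibble(kappa_T = ts$kappa_T,
                                              residual = 0)))
  }
  K <- k_from_boundary(g0, mu0)
  # coarse scan locates sign changes cheaply; Brent polishing then uses the
  # tightly integrated residual
  f_scan <- function(k) kappa_residual(k, g0, K, R, L, rtol = 1e-6,
                                       atol = 1e-8)
  f <- function(k) kappa_residual(k, g0, K, R, L)
  ks <- seq(bracket[1], bracket[2], length.out = n_scan)
  fs <- vapply(ks, f_scan, numeric(1))
  idx <- which(fs[-1] * fs[-length(fs)] < 0)
  step <- ks[2] - ks[1]
  roots <- vapply(idx, function(i) {
    polish_root(f, ks[i], ks[i + 1], step, bracket, tol)
  }, numeric(1))
  roots <- sort(unique(roots[is.finite(roots)]))
  # keep only genuine boundary roots (discard penalty-zone artefacts)
  sols <- lapply(roots, function(k) fiber_profile(g0, mu0, k, R, L))
  keep <- vapply(sols, function(sol) {
    sol$status == "ok" && abs(sol$boundary_residual) < 1e-6
  }, logical(1))
  roots <- roots[keep]; sols <- sols[keep]
  if (!length(roots)) {
    return(new_shooting_result("kappa_T", NA_real_, NULL, NA_real_, bracket,
                               "no-sign-change",
                               tibble::tibble(kappa_T = numeric(0),
                                              residual = numeric(0))))
  }
  ip <- which.min(abs(roots))
  res_tbl <- tibble::tibble(
    kappa_T = roots,
    residual = vapply(sols, function(s) s$boundary_residual, numeric(1)))
  new_shooting_result("kappa_T", roots[ip], sols[[ip]],
                      sols[[ip]]$boundary_residual, bracket, "converged",
                      res_tbl)
}

#' Inverse query: solve for the fibril angle at fixed curvature
#'
#' Root-finds `mu0` such that the shooting family at fixed `kappa_T` meets
#' the boundary. Round-trips with [solve_kappa()] to high accuracy.
#'
#' @inheritParams solve_kappa
#' @param kappa_T Fixed constant fiber curvature.
#' @param mu0_range Angle search range in degrees (open subset of (0, 90)).
#' @param n_scan Scan nodes across `mu0_range`.
#' @return A `shooting_result` with `parameter = "mu0"`.
#' @export
solve_mu0 <- function(g0, kappa_T, R = 1, L = 1.25,
                      mu0_range = c(0.5, 89.5), n_scan = 90, tol = 1e-10) {
  stopifnot(g0 > 0)
  f_scan <- function(mu0) {
    kappa_residual(kappa_T, g0, k_from_boundary(g0, mu0), R, L,
                   rtol = 1e-6, atol = 1e-8)
  }
  f <- function(mu0) {
    kappa_residual(kappa_T, g0, k_from_boundary(g0, mu0), R, L)
  }
  ms <- seq(mu0_range[1], mu0_range[2], length.out = n_scan)
  fs <- vapply(ms, f_scan, numeric(1))
  idx <- which(fs[-1] * fs[-length(fs)] < 0)
  step <- ms[2] - ms[1]
  roots <- vapply(idx, function(i) {
    polish_root(f, ms[i], ms[i + 1], step, mu0_range, tol)
  }, numeric(1))
  roots <- roots[is.finite(roots)]
  keep <- vapply(roots, function(m) {
    sol <- fiber_profile(g0, m, kappa_T, R, L)
    sol$status == "ok" && abs(sol$boundary_residual) < 1e-6
  }, logical(1))
  roots <- roots[keep]
  if (!length(roots)) {
    return(new_shooting_result("mu0", NA_real_, NULL, NA_real_, mu0_range,
                               "no-sign-change",
                               tibble::tibble(mu0 = numeric(0),
                                              residual = numeric(0))))
  }
  primary <- roots[1]
  sol <- fiber_profile(g0, primary, kappa_T, R, L)
  new_shooting_result("mu0", primary, sol, sol$boundary_residual, mu0_range,
                      "converged",
                      tibble::tibble(mu0 = roots,
                                     residual = vapply(roots, function(m) {
                                       fiber_profile(g0, m, kappa_T, R,
                                                     L)$boundary_residual
                                     }, numeric(1))))
}

#' Existence limits of the shooting family in the neck radius
#'
#' For each fibril angle, locates the smallest and largest neck radius for
#' which a boundary-satisfying solution exists (the dashed limit curves of
#' the phase diagram), refined by bisection on `g0`.
#'
#' @inheritParams solve_kappa
#' @param mu0 Vector of fibril angles (degrees).
#' @param g0_range Interval of neck radii to probe.
#' @param n_grid Initial grid resolution across `g0_range`.
#' @param resolution Bisection resolution on `g0`.
#' @param n_scan Scan nodes per solve (coarser than the default for speed).
#' @return A tibble with columns `mu0`, `side` (`"lower"`/`"upper"`), `g0`
#'   and `kappa_T` (curvature at the last solvable neck radius).
#' @export
existence_limits <- function(mu0, g0_range = c(0.05, 1.3), R = 1, L = 1.25,
                             n_grid = 26, resolution = 1e-4, n_scan = 49) {
  purrr::map_dfr(mu0, function(m) {
    gs <- seq(g0_range[1], g0_range[2], length.out = n_grid)
    ok <- vapply(gs, function(g0) {
      solve_kappa(g0, m, R, L, n_scan = n_scan)$status == "converged"
    }, logical(1))
    if (!any(ok)) {
      return(tibble::tibble(mu0 = m, side = c("lower", "upper"),
                            g0 = NA_real_, kappa_T = NA_real_))
    }
    bisect <- function(g_bad, g_good) {
      while (abs(g_good - g_bad) > resolution) {
        mid <- (g_bad + g_good) / 2
        if (solve_kappa(mid, m, R, L, n_scan = n_scan)$status ==
            "converged") g_good <- mid else g_bad <- mid
      }
      g_good
    }
    i1 <- which(ok)[1]; i2 <- rev(which(ok))[1]
    lo <- if (i1 > 1) bisect(gs[i1 - 1], gs[i1]) else gs[1]
    hi <- if (i2 < length(gs)) bisect(gs[i2 + 1], gs[i2]) else gs[length(gs)]
    tibble::tibble(
      mu0 = m, side = c("lower", "upper"), g0 = c(lo, hi),
      kappa_T = c(solve_kappa(lo, m, R, L, n_scan = n_scan)$kappa_T,
                  solve_kappa(hi, m, R, L, n_scan = n_scan)$kappa_T))
  })
}
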