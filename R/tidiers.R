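#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for solved objects
#'
#' `tidy()` returns the per-z solution table; `glance()` a one-row summary.
#'
#' @param x A `fiber_solution`, `delaunay_solution` or `shooting_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name fibershape-tidiers
NULL

#' @rdname fibershape-tidiers
#' @export
tidy.fiber_solution <- function(x, ...) {
  if (x$status != "ok" || is.null(x$data)) {
    return(tibble::tibble(z = numeric(0), g = numeric(0)))
  }
  x$data
}

#' @rdname fibershape-tidiers
#' @export
glance.fiber_solution <- function(x, ...) {
  tibble::tibble(g0 = x$g0, mu0 = x$mu0, kappa_T = x$kappa_T, K = x$K,
                 H_neck = if (x$status == "ok") x$H_neck else NA_real_,
                 pressure_sign = if (x$status == "ok") x$pressure_sign
                                 else NA_real_,
                 boundary_residual = if (x$status == "ok")
                   x$boundary_residual else NA_real_,
                 chirality = x$chirality, status = x$status)
}

#' @rdname fibershape-tidiers
#' @export
tidy.delaunay_solution <- function(x, ...) {
  if (x$status != "converged") {
    return(tibble::tibble(s = numeric(0), z = numeric(0)))
  }
  x$data
}

#' @rdname fibershape-tidiers
#' @export
glance.delaunay_solution <- function(x, ...) {
  if (x$status != "converged") {
    return(tibble::tibble(g0 = x$g0, H = NA_real_, B = NA_real_,
                          family = NA_character_, status = x$status))
  }
  tibble::tibble(g0 = x$g0, H = x$H, B = x$B, family = x$family,
                 residual = x$residual, single_valued = x$single_valued,
                 status = x$status)
}

#' @rdname fibershape-tidiers
#' @export
tidy.shooting_result <- function(x, ...) x$roots

#' @rdname fibershape-tidiers
#' @export
glance.shooting_result <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, value = x$value,
                 kappa_T = x$kappa_T,
                 residual = x$residual, status = x$status,
                 n_roots = nrow(x$roots))
}

#' Plot methods
#'
#' `autoplot()` draws the meridian silhouette of a solved shape (both
#' \eqn{\pm g(z)}), or, for a sweep, the phase diagram of neck radius
#' against fiber curvature or neck mean curvature.
#'
#' @param object A `fiber_solution`, `delaunay_solution` or
#'   `fibershape_sweep`.
#' @param x_var For sweeps: `"kappa_T"` or `"H_neck"` on the x axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fibershape-autoplot
NULL

#' @rdname fibershape-autoplot
#' @export
autoplot.fiber_solution <- function(object, ...) {
  stopifnot(object$status == "ok")
  zg <- seq(-object$L / 2, object$L / 2, length.out = 201)
  d <- tibble::tibble(z = zg, g = profile_eval(object$profile, zg))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$g)) +
    ggplot2::geom_line(ggplot2::aes(y = -.data$g)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "z (units of R)", y = "g(z)",
      title = sprintf("g0 = %.3g, mu0 = %.3g deg, kappa_T = %.4g",
                      object$g0, object$mu0, object$kappa_T))
}

#' @rdname fibershape-autoplot
#' @export
autoplot.delaunay_solution <- function(object, ...) {
  stopifnot(object$status == "converged")
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$g)) +
    ggplot2::geom_line(ggplot2::aes(y = -.data$g)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z (units of R)", y = "g(z)",
                  title = sprintf("Delaunay %s: g0 = %.3g, H = %.4g",
                                  object$family, object$g0, object$H))
}

#' @rdname fibershape-autoplot
#' @export
autoplot.fibershape_sweep <- function(object, x_var = c("kappa_T", "H_neck"),
                                      ...) {
  x_var <- match.arg(x_var)
  d <- dplyr::filter(tibble::as_tibble(object), .data$status == "converged")
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x_var]], y = .data$g0,
                                  colour = factor(.data$mu0),
                                  group = factor(.data$mu0))) +
    ggplot2::geom_path() +
    ggplot2::labs(x = if (x_var == "kappa_T") "fiber curvature kappa_T"
                      else "mean curvature at the neck",
                  y = "neck radius g0", colour = "mu0 (deg)")
}

#' Phase-diagram plot with reference landmarks
#'
#' Wraps [autoplot.fibershape_sweep()] and overlays the single-sphere
#' landmark and the cylinder line.
#'
#' @param sweep A [sweep_iso_mu0()] result.
#' @inheritParams fibershape-autoplot
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(sweep, x_var = c("kappa_T", "H_neck")) {
  x_var <- match.arg(x_var)
  R <- attr(sweep, "R") %||% 1
  L <- attr(sweep, "L") %||% 1.25
  ss <- sphere_segment(R, L)
  landmark_x <- if (x_var == "kappa_T") ss$kappa_T else 1 / ss$rho
  autoplot(sweep, x_var = x_var) +
    ggplot2::annotate("point", x = landmark_x, y = ss$rho, shape = 19,
                      size = 2) +
    ggplot2::geom_hline(yintercept = R, linetype = "dashed")
}
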