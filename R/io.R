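#' Read and write meridian profiles as CSV
#'
#' The on-disk format is a UTF-8 CSV with header `z,g,g_prime`
#' ('.' decimal separator). Values survive a round trip to better than
#' 1e-12.
#'
#' @param profile A [profile_curve()].
#' @param path File path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   returns a [profile_curve()].
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(profile[, c("z", "g", "g_prime")], path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  profile_curve(d$z, d$g, d$g_prime)
}

#' Read and write space curves as CSV
#'
#' Columns `t, x, y, z` where `t` is the curve parameter.
#'
#' @param curve A data frame with columns `x`, `y`, `z` and optionally `t`
#'   (defaults to `z`).
#' @param path File path.
#' @return The path (write) or a tibble (read).
#' @export
write_space_curve_csv <- function(curve, path) {
  t <- if ("t" %in% names(curve)) curve$t else curve$z
  readr::write_csv(tibble::tibble(t = t, x = curve$x, y = curve$y,
                                  z = curve$z), path)
  invisible(path)
}

#' @rdname write_space_curve_csv
#' @export
read_space_curve_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Export a solved equilibrium as CSV plus JSON metadata
#'
#' Writes `<prefix>.csv` with columns `z, g, g_prime, theta, alpha` and a
#' sidecar `<prefix>_meta.json` carrying `g0`, `mu0`, `kappa_T`, `K`,
#' `H_neck`, `L`, `R` and the chirality.
#'
#' @param solution A successful [fiber_profile()] result.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_fiber_solution <- function(solution, prefix) {
  stopifnot(inherits(solution, "fiber_solution"), solution$status == "ok")
  csv <- paste0(prefix, ".csv"); meta <- paste0(prefix, "_meta.json")
  readr::write_csv(solution$data[, c("z", "g", "g_prime", "theta", "alpha")],
                   csv)
  jsonlite::write_json(
    list(g0 = solution$g0, mu0 = solution$mu0, kappa_T = solution$kappa_T,
         K = solution$K, H_neck = solution$H_neck, L = solution$L,
         R = solution$R, chirality = solution$chirality),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, meta))
}

#' Triangulated surface mesh (OBJ) of a solved shape
#'
#' Revolves the meridian into a watertight-in-\eqn{\theta} triangulated tube
#' on an `n_theta` by `n_z` grid and writes Wavefront OBJ; fiber paths are
#' appended as OBJ polylines (`l` elements). An open tube has Euler
#' characteristic 0, which is verified combinatorially and reported.
#'
#' @param x A `fiber_solution`, `delaunay_solution` or [profile_curve()].
#' @param path Output `.obj` path.
#' @param n_theta,n_z Angular and axial resolution.
#' @param n_fibers Number of fiber polylines to append (fiber solutions
#'   only).
#' @return Invisibly, a list with `n_vertices`, `n_triangles`, `euler`.
#' @export
export_mesh <- function(x, path, n_theta = 64, n_z = 65, n_fibers = 0) {
  profile <- if (inherits(x, "profile_curve")) x else x$profile
  if (is.null(profile)) stop("no profile available to mesh", call. = FALSE)
  zr <- range(profile$z)
  zs <- seq(zr[1], zr[2], length.out = n_z)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  g <- profile_eval(profile, zs)
  if (any(!is.finite(g)) || any(g <= 0)) {
    stop("degenerate profile: cannot export mesh", call. = FALSE)
  }
  verts <- do.call(rbind, lapply(seq_along(zs), function(i) {
    cbind(g[i] * cos(th), g[i] * sin(th), zs[i])
  }))
  vid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  tris <- do.call(rbind, lapply(seq_len(n_z - 1L), function(i) {
    do.call(rbind, lapply(seq_len(n_theta), function(j) {
      rbind(c(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
            c(vid(i, j + 1L), vid(i + 1L, j + 1L), vid(i + 1L, j)))
    }))
  }))
  lines <- c("# fibershape surface mesh",
             sprintf("v %.10g %.10g %.10g", verts[, 1], verts[, 2],
                     verts[, 3]),
             sprintf("f %d %d %d", tris[, 1], tris[, 2], tris[, 3]))
  if (n_fibers > 0 && inherits(x, "fiber_solution") && !is.null(x$data)) {
    fam <- fiber_family(x, n_fibers)
    off <- nrow(verts)
    for (k in seq_len(n_fibers)) {
      fc <- fam[fam$fiber == k, ]
      lines <- c(lines,
                 sprintf("v %.10g %.10g %.10g", fc$x, fc$y, fc$z),
                 paste("l", paste(off + seq_len(nrow(fc)), collapse = " ")))
      off <- off + nrow(fc)
    }
  }
  writeLines(lines, path)
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  edges <- unique(t(apply(edges, 1, sort)))
  invisible(list(n_vertices = nrow(verts), n_triangles = nrow(tris),
                 euler = nrow(verts) - nrow(edges) + nrow(tris)))
}

#' Run configuration with YAML round trip
#'
#' Bundles the geometry, solver tolerances, sweep grids, chirality and seed
#' used by the command-line interface. `read_run_config(write_run_config(x))`
#' reproduces `x` exactly.
#'
#' @param R,L Boundary geometry.
#' @param rtol,atol Integration tolerances.
#' @param kappa_bracket,n_scan Shooting bracket and scan resolution.
#' @param chirality `"right"` or `"left"`.
#' @param mu0_grid,g0_grid Default sweep grids.
#' @param out_dir Output directory.
#' @param seed Seed for property-test sampling (the solver itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(R = 1, L = 1.25, rtol = 1e-10, atol = 1e-12,
                       kappa_bracket = c(-20, 20), n_scan = 97,
                       chirality = "right",
                       mu0_grid = c(0, 10, 20, 30, 35, 40, 50, 58, 70),
                       g0_grid = seq(0.05, 1.17, by = 0.01),
                       out_dir = ".", seed = 1L) {
  structure(list(R = R, L = L, rtol = rtol, atol = atol,
                 kappa_bracket = kappa_bracket, n_scan = as.integer(n_scan),
                 chirality = chirality, mu0_grid = mu0_grid,
                 g0_grid = g0_grid, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  # emit doubles with 17 significant digits so the YAML round trip is exact;
  # a decimal point is forced so the loader reads them back as floats
  handlers <- list(numeric = function(x) {
    s <- sprintf("%.17g", x)
    plain <- !grepl("\\.", s)
    s[plain] <- sub("^([-+]?[0-9]+)", "\\1.0", s[plain])
    structure(s, class = "verbatim")
  })
  writeLines(yaml::as.yaml(unclass(config), handlers = handlers), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' Deterministic catalog of reference-shape fixtures
#'
#' Generates one randomized, valid member of every closed-form family used
#' as an oracle — sphere, cylinder, hyperboloid, catenoid, torus segment,
#' unduloid, nodoid, and two- and three-segment sphere stacks — reproducibly
#' from a seed. Intended for property-style testing.
#'
#' @param seed Integer seed.
#' @return A tibble with columns `family`, `params` (list) and `profile`
#'   (list of [profile_curve()] or `NULL` for curve-only fixtures).
#' @export
fixture_suite <- function(seed = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(seed)
  R <- 1; L <- 1.25
  rows <- list()
  add <- function(family, params, profile) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      family = family, params = list(params), profile = list(profile))
  }
  ss <- sphere_segment(R, L)
  add("sphere", list(rho = ss$rho, kappa_T = ss$kappa_T), ss$profile)
  mu_cyl <- stats::runif(1, 5, 60)
  add("cylinder", list(R = R, mu0 = mu_cyl,
                       kappa_T = sin(mu_cyl * pi / 180)^2),
      cylinder_solution(R, L, mu_cyl)$profile)
  g0h <- stats::runif(1, 0.3, 0.9)
  hy <- hyperboloid_shape(g0h, R, L)
  add("hyperboloid", list(g0 = g0h, mu0 = hy$mu0, m = hy$m), hy$profile)
  cn <- catenoid_neck(R, L)
  add("catenoid", list(c = cn$c), cn$profile)
  g0t <- sample(c(stats::runif(1, 0.4, 0.9), stats::runif(1, 1.05, 1.15)), 1)
  to <- torus_segment(g0t, R, L)
  add("torus", list(g0 = g0t, kappa_T = to$kappa_T, r_arc = to$r_arc),
      to$profile)
  # free (non boundary-matched) Delaunay members from the first integral
  g0u <- stats::runif(1, 0.35, 0.6); Hu <- stats::runif(1, 0.55, 0.9)
  add("unduloid", list(g0 = g0u, H = Hu, B = g0u - Hu * g0u^2),
      delaunay_free_profile(g0u, Hu, L))
  g0n <- stats::runif(1, 0.35, 0.6); Hn <- -stats::runif(1, 0.2, 0.5)
  add("nodoid", list(g0 = g0n, H = Hn, B = g0n - Hn * g0n^2),
      delaunay_free_profile(g0n, Hn, L))
  g02 <- stats::runif(1, 0.5, 1.0)
  st2 <- stacked_spheres(2, R, L, g02)
  add("stack2", list(g0 = g02, kappa_T = st2$kappa_T, rho = st2$rho),
      st2$profile)
  g03 <- stats::runif(1, 1.02, 1.15)
  st3 <- stacked_spheres(3, R, L, g03)
  add("stack3", list(g0 = g03, kappa_T = st3$kappa_T, rho = st3$rho),
      st3$profile)
  dplyr::bind_rows(rows)
}

# integrate a CMC meridian from a neck without boundary matching, stopping
# before any vertical tangent so the profile stays single-valued in z
delaunay_free_profile <- function(g0, H, L, n = 201) {
  out <- deSolve::lsodar(
    y = c(z = 0, g = g0, psi = 0), times = seq(0, 3 * L, length.out = 1001),
    func = delaunay_ode_func, parms = list(H = H),
    rootfunc = function(s, y, parms) {
      c(abs(y[3]) - (pi / 2 - 0.05), y[1] - L / 2)
    },
    rtol = 1e-12, atol = 1e-13)
  dat <- tibble::tibble(z = out[, 2], g = out[, 3], psi = out[, 4])
  dat <- dat[!duplicated(dat$z), ]
  zmax <- max(dat$z)
  psi_of_z <- stats::splinefun(dat$z, dat$psi, method = "natural")
  g_of_z <- stats::splinefun(dat$z, dat$g, method = "natural")
  zg <- seq(-zmax, zmax, length.out = n)
  za <- abs(zg)
  psi_a <- psi_of_z(za); g_a <- g_of_z(za)
  profile_curve(zg, g_a, sign(zg) * tan(psi_a),
                (cos(psi_a) / g_a - 2 * H) / cos(psi_a)^3)
}
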