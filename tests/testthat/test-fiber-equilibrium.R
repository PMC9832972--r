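test_that("K follows Clairaut's relation at the neck", {
  expect_equal(k_from_boundary(0.5, 30), 16, tolerance = 1e-14)
  expect_equal(k_from_boundary(1.17925, 58) * 1.17925^2,
               1 / sin(58 * pi / 180)^2, tolerance = 1e-12)
  expect_equal(k_from_boundary(1.17925, 58) * 1.17925^2, 1.390,
               tolerance = 1e-3)
  # sin -> 1 limit
  expect_equal(k_from_boundary(1, 89.999), 1, tolerance = 1e-6)
  expect_error(k_from_boundary(1, 0), "meridian-fiber limit")
  expect_error(k_from_boundary(1, 90), "must be < 90")
})

test_that("the cylinder is a fixed point of the meridian equation", {
  for (mu0 in c(10, 20, 45, 70)) {
    K <- k_from_boundary(1, mu0)
    r <- fiber_rhs(1, 0, K, sin(mu0 * pi / 180)^2)
    expect_equal(r$g_double_prime, 0, tolerance = 1e-13)
    # neck winding rate theta'(0) = tan(mu0)/g0
    expect_equal(r$theta_prime, tan(mu0 * pi / 180), tolerance = 1e-12)
  }
})

test_that("closed-form profiles satisfy the meridian equation pointwise", {
  z <- seq(-0.6, 0.6, length.out = 81)
  # hyperboloid: kappa_T = 0
  hy <- hyperboloid_shape(0.8, REF_R, REF_L)
  K <- k_from_boundary(0.8, hy$mu0)
  r <- fiber_rhs(profile_eval(hy$profile, z), profile_eval(hy$profile, z, 1),
                 K, 0)
  expect_lt(max(abs(r$g_double_prime - profile_eval(hy$profile, z, 2))),
            1e-9)
  # sphere: kappa_T = +1/rho, for any fibril angle
  ss <- sphere_segment(REF_R, REF_L)
  for (mu0 in c(20, 40, 57)) {
    Ks <- k_from_boundary(ss$rho, mu0)
    rs <- fiber_rhs(profile_eval(ss$profile, z),
                    profile_eval(ss$profile, z, 1), Ks, ss$kappa_T)
    expect_lt(max(abs(rs$g_double_prime - profile_eval(ss$profile, z, 2))),
              1e-8)
  }
  expect_error(fiber_rhs(0.2, 0, k_from_boundary(0.5, 30), 0),
               "singular set")
})

test_that("integration reproduces the sphere, hyperboloid and cylinder", {
  ss <- sphere_segment(REF_R, REF_L)
  fs <- fiber_profile(ss$rho, 30, ss$kappa_T)
  expect_equal(fs$status, "ok")
  expect_lt(abs(fs$boundary_residual), 1e-6)
  expect_equal(fs$H_neck, 1 / ss$rho, tolerance = 1e-10)

  for (g0 in c(0.4, 0.6, 0.8)) {
    m <- (REF_R^2 - g0^2) / (REF_L / 2)^2
    mu0 <- atan(sqrt(m)) * 180 / pi
    fh <- fiber_profile(g0, mu0, 0)
    expect_lt(abs(fh$boundary_residual), 1e-6)
    z <- fh$data$z
    expect_lt(max(abs(fh$data$g - sqrt(g0^2 + m * z^2))), 1e-8)
  }

  fc <- fiber_profile(1, 20, sin(20 * pi / 180)^2)
  expect_lt(max(abs(fc$data$g - 1)), 1e-10)
})

test_that("integration failures carry the position and mode", {
  # strong positive curvature at a thin neck pinches off / hits the
  # singular set before reaching the boundary
  bad <- fiber_profile(0.3, 35, 5)
  expect_equal(bad$status, "failed")
  expect_true(bad$failure_mode %in% c("singular", "pinch", "steep"))
  expect_true(bad$failure_z >= 0 && bad$failure_z < REF_L / 2)
})

test_that("solutions are symmetric and conserve Clairaut's relation", {
  sols <- list(
    fiber_profile(0.6, 35, solve_kappa(0.6, 35)$kappa_T),
    fiber_profile(1.1, 25, solve_kappa(1.1, 25)$kappa_T))
  for (fs in sols) {
    d <- fs$data
    # g even, theta odd
    expect_equal(d$g, rev(d$g), tolerance = 1e-12)
    expect_equal(d$theta, -rev(d$theta), tolerance = 1e-12)
    # Clairaut: g sin(alpha) constant
    clair <- d$g * sin(d$alpha)
    expect_lt(diff(range(clair)), 1e-8)
    expect_equal(clair[1], fs$g0 * sin(fs$mu0 * pi / 180), tolerance = 1e-10)
  }
})

test_that("alpha from Clairaut matches the geometric fiber-meridian angle", {
  fs <- fiber_profile(0.7, 40, solve_kappa(0.7, 40)$kappa_T)
  fc <- fiber_curve(fs)
  d <- fs$data
  # meridian unit direction at each fiber point
  s <- sqrt(1 + d$g_prime^2)
  th <- d$theta
  mx <- d$g_prime * cos(th) / s; my <- d$g_prime * sin(th) / s; mz <- 1 / s
  cosa <- fc$tx * mx + fc$ty * my + fc$tz * mz
  expect_lt(max(abs(acos(pmin(1, cosa)) - d$alpha)), 1e-8)
})

test_that("reconstructed fibers have constant curvature kappa_T and are
          geodesics", {
  cases <- list(c(g0 = 0.6, mu0 = 35), c(g0 = 1.1, mu0 = 45),
                c(g0 = 0.85, mu0 = 20))
  for (cs in cases) {
    sk <- solve_kappa(cs[["g0"]], cs[["mu0"]])
    expect_equal(sk$status, "converged")
    fc <- fiber_curve(sk$solution)
    expect_lt(max(abs(fc$kappa - abs(sk$kappa_T))), 1e-6)
    cr <- colinearity_residual(fc, sk$solution$profile)
    expect_lt(max(cr$residual), 1e-8)
    # signed curvature matches the solver's kappa_T (sign convention)
    expect_lt(max(abs(cr$kappa_signed - sk$kappa_T)), 1e-6)
  }
})

test_that("cylindrical and Cartesian formulations agree pointwise", {
  set.seed(421)
  n_ok <- 0
  for (i in 1:25) {
    g0 <- runif(1, 0.45, 1.15)
    mu0 <- runif(1, 10, 55)
    sk <- try(solve_kappa(g0, mu0), silent = TRUE)
    if (inherits(sk, "try-error") || sk$status != "converged") next
    fc <- fiber_curve(sk$solution)
    half <- fc[fc$z >= -1e-12, ]
    cart <- fiber_cartesian(g0, mu0, sk$kappa_T, REF_L,
                            n_out = nrow(half))
    expect_s3_class(cart, "space_curve")
    d <- sqrt((cart$x - half$x)^2 + (cart$y - half$y)^2 +
                (cart$z - half$z)^2)
    expect_lt(max(d), 1e-6)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 20)
})

test_that("Cartesian oracle: zero curvature gives straight rulings and the
          sphere case stays on the sphere", {
  g0 <- 0.7
  m <- (REF_R^2 - g0^2) / (REF_L / 2)^2
  mu0 <- atan(sqrt(m)) * 180 / pi
  cart <- fiber_cartesian(g0, mu0, 0, REF_L)
  # straight line: x constant, y linear in z
  expect_lt(max(abs(cart$x - g0)), 1e-9)
  expect_lt(max(abs(cart$y - sqrt(m) * cart$z)), 1e-9)
  expect_true(all(cart$kappa == 0))

  ss <- sphere_segment(REF_R, REF_L)
  cs <- fiber_cartesian(ss$rho, 30, ss$kappa_T, REF_L)
  expect_lt(max(abs(sqrt(cs$x^2 + cs$y^2 + cs$z^2) - ss$rho)), 1e-8)
  expect_lt(diff(range(cs$kappa)), 1e-6)
})

test_that("fiber families are congruent under rotation", {
  sk <- solve_kappa(0.8, 30)
  fam <- fiber_family(sk$solution, 4)
  expect_equal(unique(fam$fiber), 1:4)
  base <- fam[fam$fiber == 1, ]
  for (k in 2:4) {
    phi <- 2 * pi * (k - 1) / 4
    rot <- fam[fam$fiber == k, ]
    expect_equal(rot$x, base$x * cos(phi) - base$y * sin(phi),
                 tolerance = 1e-9)
    expect_equal(rot$y, base$x * sin(phi) + base$y * cos(phi),
                 tolerance = 1e-9)
    cr <- colinearity_residual(fiber_curve(sk$solution, theta0 = phi),
                               sk$solution$profile)
    expect_lt(max(cr$residual), 1e-8)
  }
  # n = 1 is the base fiber
  f1 <- fiber_family(sk$solution, 1)
  expect_equal(f1$x, base$x)
})

test_that("chirality flag mirrors the winding without changing the shape", {
  kap <- solve_kappa(0.8, 30)$kappa_T
  right <- fiber_profile(0.8, 30, kap)
  left <- fiber_profile(0.8, 30, kap, chirality = "left")
  expect_equal(right$data$g, left$data$g)
  expect_equal(right$data$theta, -left$data$theta)
})
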