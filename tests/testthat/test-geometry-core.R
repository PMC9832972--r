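test_that("surface_point maps (theta, z) onto the surface of revolution", {
  cyl <- profile_from_function(function(z) rep(1, length(z)), c(-1, 1),
                               function(z) rep(0, length(z)),
                               function(z) rep(0, length(z)))
  expect_equal(unlist(surface_point(cyl, 0, 0)), c(x = 1, y = 0, z = 0))
  expect_equal(unlist(surface_point(cyl, pi / 2, 0.5)),
               c(x = 0, y = 1, z = 0.5), tolerance = 1e-12)
  # boundary circle of the single spherical segment
  ss <- sphere_segment(REF_R, REF_L)
  p <- surface_point(ss$profile, 0, REF_L / 2)
  expect_equal(p$x, sqrt(REF_RHO^2 - (REF_L / 2)^2), tolerance = 1e-12)
  expect_equal(p$x, 1.0, tolerance = 1e-9)
  expect_error(surface_point(cyl, 0, 2), "out of the profile range")
})

test_that("surface_normal is outward, unit, and orthogonal to the tangents", {
  cyl <- profile_from_function(function(z) rep(1, length(z)), c(-1, 1),
                               function(z) rep(0, length(z)),
                               function(z) rep(0, length(z)))
  n <- surface_normal(cyl, c(0, 1, 2), c(0, 0.2, -0.4))
  expect_equal(n$nx, cos(c(0, 1, 2)), tolerance = 1e-14)
  expect_equal(n$ny, sin(c(0, 1, 2)), tolerance = 1e-14)
  expect_equal(n$nz, rep(0, 3), tolerance = 1e-14)

  ss <- sphere_segment(REF_R, REF_L)
  z <- seq(-0.6, 0.6, length.out = 11)
  n <- surface_normal(ss$profile, 0, z)
  # sphere normal passes through the centre
  expect_equal(n$nx, profile_eval(ss$profile, z) / REF_RHO, tolerance = 1e-12)
  expect_equal(n$nz, z / REF_RHO, tolerance = 1e-12)

  cat <- catenoid_neck(REF_R, REF_L)
  z <- seq(-0.5, 0.5, length.out = 21)
  n <- surface_normal(cat$profile, 0.7, z)
  fr <- surface_frame(cat$profile, 0.7, z)
  dot_meridian <- n$nx * fr$e2x + n$ny * fr$e2y + n$nz * fr$e2z
  expect_lt(max(abs(dot_meridian)), 1e-12)
  expect_unit_vectors(n$nx, n$ny, n$nz)
})

test_that("surface_frame is a right-handed orthonormal triad", {
  cat <- catenoid_neck(REF_R, REF_L)
  fr <- surface_frame(cat$profile, seq(0, 6, length.out = 13),
                      seq(-0.55, 0.55, length.out = 13))
  expect_unit_vectors(fr$e1x, fr$e1y, fr$e1z)
  expect_unit_vectors(fr$e2x, fr$e2y, fr$e2z)
  expect_unit_vectors(fr$e3x, fr$e3y, fr$e3z)
  # e1 x e2 = e3
  cx <- fr$e1y * fr$e2z - fr$e1z * fr$e2y
  cy <- fr$e1z * fr$e2x - fr$e1x * fr$e2z
  cz <- fr$e1x * fr$e2y - fr$e1y * fr$e2x
  expect_lt(max(abs(cx - fr$e3x), abs(cy - fr$e3y), abs(cz - fr$e3z)), 1e-10)
  # pairwise orthogonality
  expect_lt(max(abs(fr$e1x * fr$e2x + fr$e1y * fr$e2y + fr$e1z * fr$e2z)),
            1e-10)
  expect_lt(max(abs(fr$e1x * fr$e3x + fr$e1y * fr$e3y + fr$e1z * fr$e3z)),
            1e-10)
})

test_that("curve_frame recovers circle curvature 1/r to 1e-10", {
  for (r in c(0.1, 1, 10)) {
    fc <- curve_frame(circle_pts(r))
    expect_lt(max(abs(fc$kappa - 1 / r)), 1e-10 * max(1, 1 / r))
    # principal normal points to the centre
    expect_lt(max(abs(fc$px + fc$x / r)), 1e-10)
    expect_lt(max(abs(fc$py + fc$y / r)), 1e-10)
  }
})

test_that("curve_frame: helix crossing the waist at angle mu has curvature
          sin^2(mu)", {
  for (mu_deg in c(20, 35, 60)) {
    mu <- mu_deg * pi / 180
    z <- seq(-0.5, 0.5, length.out = 101)
    w <- tan(mu)
    pts <- tibble::tibble(
      x = cos(w * z), y = sin(w * z), z = z,
      xp = -w * sin(w * z), yp = w * cos(w * z),
      xpp = -w^2 * cos(w * z), ypp = -w^2 * sin(w * z))
    fc <- curve_frame(pts)
    expect_lt(max(abs(fc$kappa - sin(mu)^2)), 1e-12)
  }
})

test_that("curve_frame flags straight segments instead of guessing a frame", {
  ruling <- hyperboloid_ruling(0.6, REF_R, REF_L)
  fc <- curve_frame(ruling)
  expect_true(all(fc$kappa == 0))
  expect_false(any(fc$frame_defined))
  expect_true(all(is.na(fc$px)))
})

test_that("curve_frame tangent and principal normal are orthonormal", {
  pts <- great_circle_pts(REF_RHO, 40)
  fc <- curve_frame(pts)
  expect_unit_vectors(fc$tx, fc$ty, fc$tz)
  expect_unit_vectors(fc$px, fc$py, fc$pz, tol = 1e-10)
  expect_lt(max(abs(fc$tx * fc$px + fc$ty * fc$py + fc$tz * fc$pz)), 1e-10)
})

test_that("colinearity residual vanishes on geodesics", {
  ss <- sphere_segment(REF_R, REF_L)
  gc <- colinearity_residual(curve_frame(great_circle_pts(REF_RHO, 30)),
                             ss$profile)
  expect_lt(max(gc$residual), 1e-10)
  # meridians of any surface of revolution are geodesics
  cat <- catenoid_neck(REF_R, REF_L)
  mr <- colinearity_residual(curve_frame(meridian_pts(cat$profile)),
                             cat$profile)
  expect_lt(max(mr$residual), 1e-10)
})

test_that("latitude circles are not geodesics: residual equals |z|/rho", {
  ss <- sphere_segment(REF_R, REF_L)
  for (z0 in c(0.2, 0.45, -0.35)) {
    lat <- circle_pts(profile_eval(ss$profile, z0), z0 = z0)
    cr <- colinearity_residual(curve_frame(lat), ss$profile)
    expect_equal(cr$residual, rep(abs(z0) / REF_RHO, nrow(cr)),
                 tolerance = 1e-9)
  }
  # the equator is the exception (a great circle)
  eq <- circle_pts(REF_RHO, z0 = 0)
  cr0 <- colinearity_residual(curve_frame(eq), ss$profile)
  expect_lt(max(cr0$residual), 1e-10)
})

test_that("colinearity_residual rejects curves off the surface", {
  ss <- sphere_segment(REF_R, REF_L)
  off <- circle_pts(1.3, z0 = 0)
  expect_error(colinearity_residual(curve_frame(off), ss$profile),
               "does not lie on the surface")
})

test_that("mean_curvature matches closed forms for the classic surfaces", {
  z <- seq(-0.6, 0.6, length.out = 41)
  cyl <- profile_from_function(function(zz) rep(1, length(zz)), c(-1, 1),
                               function(zz) rep(0, length(zz)),
                               function(zz) rep(0, length(zz)))
  expect_equal(mean_curvature(cyl, z), rep(0.5, 41), tolerance = 1e-12)
  ss <- sphere_segment(REF_R, REF_L)
  expect_equal(mean_curvature(ss$profile, z), rep(1 / REF_RHO, 41),
               tolerance = 1e-8)
  expect_equal(1 / REF_RHO, 0.848, tolerance = 1e-3)
  cat <- catenoid_neck(REF_R, REF_L)
  expect_lt(max(abs(mean_curvature(cat$profile, z))), 1e-8)
  expect_equal(cat$c, 0.7035, tolerance = 1e-3)
})

test_that("profile interpolation honours stored derivatives", {
  ss <- sphere_segment(REF_R, REF_L)
  # numeric profile without closures: rebuild from the grid only
  num <- profile_curve(ss$profile$z, ss$profile$g, ss$profile$g_prime,
                       ss$profile$g_double_prime)
  z <- seq(-0.6, 0.6, length.out = 503)
  expect_lt(max(abs(profile_eval(num, z) - sqrt(REF_RHO^2 - z^2))), 1e-9)
  expect_lt(max(abs(profile_eval(num, z, 1) + z / sqrt(REF_RHO^2 - z^2))),
            1e-7)
  expect_silent(validate_profile(num))
  expect_error(profile_curve(c(0, 0, 1), c(1, 1, 1)), "strictly increasing")
  expect_error(profile_curve(c(0, 1), c(1, -1)), "positive")
})
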