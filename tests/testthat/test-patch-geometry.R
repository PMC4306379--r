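test_that("shape deltas follow the semiaxis definitions", {
  expect_equal(unname(unlist(shape_deltas(unit_sphere_half())[1:2])), c(0, 0))
  expect_equal(unname(unlist(shape_deltas(revolution_half())[1:2])), c(0.75, 0))
  d <- shape_deltas(ellipsoid_patch(3, 2, 1))
  expect_equal(d$delta1, 8 / 9)
  expect_equal(d$delta2, 3 / 4)
})

test_that("delta ordering 1 > delta1 >= delta2 >= 0 holds on random specs", {
  set.seed(42)
  for (i in 1:50) {
    a <- sort(runif(3, 0.3, 5), decreasing = TRUE)
    s <- ellipsoid_patch(a[1], a[2], a[3])
    expect_true(s$delta1 < 1)
    expect_true(s$delta1 >= s$delta2)
    expect_true(s$delta2 >= 0)
  }
})

test_that("invalid specs are rejected with the violated invariant named", {
  expect_error(ellipsoid_patch(1, 2, 1), "a1 >= a2 >= a3")
  expect_error(ellipsoid_patch(1, 1, 0), "a1 >= a2 >= a3")
  expect_error(ellipsoid_patch(1, 1, 1, alpha1 = 2), "alpha")
  expect_error(ellipsoid_patch(1, 1, 1, beta1 = 3), "beta")
  expect_error(ellipsoid_patch(1, 1, 1, alpha1 = -1, alpha2 = 1), "alpha2 < alpha1")
  expect_error(ellipsoid_patch(1, 1, 1, beta1 = -1, beta2 = 1), "beta2 < beta1")
})

test_that("surface_point lifts to the upper half-ellipsoid", {
  sp <- unit_sphere_half()
  expect_equal(as.numeric(surface_point(sp, 0, 0)), c(0, 0, 1))
  expect_equal(as.numeric(surface_point(sp, 1, 0)), c(1, 0, 0))
  expect_equal(as.numeric(surface_point(sp, 0.5, 0.5)),
               c(0.5, 0.5, sqrt(0.5)))
  expect_error(surface_point(sp, 1.5, 0), "outside")
  rev <- revolution_half()
  p <- surface_point(rev, 0.3, -0.2)
  expect_equal((p$px / 2)^2 + p$py^2 + p$pz^2, 1, tolerance = 1e-12)
  expect_gte(p$pz, 0)
})

test_that("g and g_inverse are mutually inverse bijections D <-> D_g", {
  for (spec in list(unit_sphere_octant(), revolution_half(), general_patch())) {
    set.seed(7)
    y1 <- runif(1000, spec$beta2 / spec$a1, spec$beta1 / spec$a1)
    y2 <- runif(1000, spec$alpha2, spec$alpha1)
    x <- map_g_inverse(spec, y1, y2)
    # independent forward map solved from the definition of g^{-1}:
    # y1 = x1/a1, y2 = x2/(a2 sqrt(1 - y1^2))
    expect_equal(x$x1 / spec$a1, y1, tolerance = 1e-12)
    expect_equal(x$x2 / (spec$a2 * sqrt(1 - y1^2)), y2, tolerance = 1e-12)
    y <- map_g(spec, x$x1, x$x2)
    expect_equal(y$y1, y1, tolerance = 1e-12)
    expect_equal(y$y2, y2, tolerance = 1e-12)
  }
})

test_that("density_f is >= 1 unnormalized with its minimum at the origin", {
  for (spec in list(unit_sphere_half(), revolution_half(), general_patch())) {
    g <- expand.grid(x1 = seq(-0.5, 0.5, length.out = 11) * spec$a1,
                     x2 = seq(-0.5, 0.5, length.out = 11) * spec$a2 * 0.8)
    keep <- (g$x1 / spec$a1)^2 + (g$x2 / spec$a2)^2 < 0.9 &
      g$x1 > spec$beta2 & g$x1 < spec$beta1
    f <- density_f(spec, g$x1[keep], g$x2[keep])
    expect_true(all(f >= 1 - 1e-12))
    expect_equal(density_f(spec, 0, 0), 1)
    expect_equal(min(f), 1)  # grid contains the origin
  }
  # grows toward the equator
  sp <- unit_sphere_half()
  expect_gt(density_f(sp, 0.999, 0), density_f(sp, 0.9, 0))
})

test_that("sphere and revolution reductions of density_fg are exact", {
  sp <- unit_sphere_half()
  y2 <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(density_fg(sp, rep(0.3, length(y2)), y2),
               sp$a1^2 / sqrt(1 - y2^2))
  rev <- revolution_half()
  y1 <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(density_fg(rev, y1, rep(0.5, length(y1))),
               rev$a1 * rev$a2 * sqrt(1 - rev$delta1 * y1^2) / sqrt(1 - 0.25))
})

test_that("density_fg equals density_f times the Jacobian of g_inverse", {
  spec <- general_patch()
  set.seed(11)
  y1 <- runif(1000, spec$beta2 / spec$a1 + 0.05, spec$beta1 / spec$a1 - 0.05)
  y2 <- runif(1000, spec$alpha2 + 0.05, spec$alpha1 - 0.05)
  h <- 1e-6
  # central finite-difference Jacobian of (y1,y2) -> (x1,x2)
  jac <- function(y1, y2) {
    gx <- function(a, b) map_g_inverse(spec, a, b)
    dx1_dy1 <- (gx(y1 + h, y2)$x1 - gx(y1 - h, y2)$x1) / (2 * h)
    dx2_dy1 <- (gx(y1 + h, y2)$x2 - gx(y1 - h, y2)$x2) / (2 * h)
    dx1_dy2 <- (gx(y1, y2 + h)$x1 - gx(y1, y2 - h)$x1) / (2 * h)
    dx2_dy2 <- (gx(y1, y2 + h)$x2 - gx(y1, y2 - h)$x2) / (2 * h)
    abs(dx1_dy1 * dx2_dy2 - dx1_dy2 * dx2_dy1)
  }
  x <- map_g_inverse(spec, y1, y2)
  lhs <- density_fg(spec, y1, y2)
  rhs <- density_f(spec, x$x1, x$x2) * jac(y1, y2)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("patch_area matches closed-form sphere and spheroid areas", {
  expect_equal(patch_area(unit_sphere_half()), 2 * pi, tolerance = 1e-8)
  expect_equal(patch_area(unit_sphere_octant()), pi / 2, tolerance = 1e-8)
  # prolate spheroid a=2, b=c=1: half of the classical closed-form area
  a <- 2; b <- 1; e <- sqrt(1 - b^2 / a^2)
  half_area <- pi * b^2 * (1 + (a / (b * e)) * asin(e))
  expect_equal(patch_area(revolution_half()), half_area, tolerance = 1e-6)
})

test_that("patch_area is additive under splitting the domain at beta = 0", {
  for (spec in list(unit_sphere_half(), revolution_half(), general_patch())) {
    lower <- ellipsoid_patch(spec$a1, spec$a2, spec$a3, spec$alpha1,
                             spec$alpha2, beta1 = 0, beta2 = spec$beta2)
    upper <- ellipsoid_patch(spec$a1, spec$a2, spec$a3, spec$alpha1,
                             spec$alpha2, beta1 = spec$beta1, beta2 = 0)
    expect_equal(patch_area(lower) + patch_area(upper), patch_area(spec),
                 tolerance = 1e-8)
  }
})

test_that("normalized density integrates to 1 over D (independent quadrature)", {
  spec <- ellipsoid_patch(2, 1, 1, alpha1 = 0.5, alpha2 = -0.5,
                          beta1 = 1, beta2 = -1)
  # nested quadrature in the original x-coordinates, independent of the
  # y-space quadrature used by patch_area
  inner <- function(x1) {
    vapply(x1, function(x) {
      lim <- spec$alpha1 * spec$a2 * sqrt(1 - (x / spec$a1)^2)
      stats::integrate(function(x2) density_f(spec, rep(x, length(x2)), x2,
                                              normalized = TRUE),
                       -lim, lim, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  total <- stats::integrate(inner, spec$beta2, spec$beta1, rel.tol = 1e-8)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("patch configs round-trip bit-exactly", {
  spec <- ellipsoid_patch(pi, exp(1), sqrt(2), alpha1 = 1 / 3, alpha2 = -2 / 7,
                          beta1 = 3, beta2 = -1 / 9)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_patch_config(spec, path)
  back <- read_patch_config(path)
  for (k in c("a1", "a2", "a3", "alpha1", "alpha2", "beta1", "beta2"))
    expect_identical(back[[k]], spec[[k]])
})
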