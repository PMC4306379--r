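# Unit-scale sampler tests; the heavier distributional checks at the study
# sizes live in test-acceptance.R.

test_that("sphere inverse transform reproduces its closed-form endpoints", {
  sp <- unit_sphere_octant()
  # U1 = 0 / 1 map to the beta endpoints; U2 = 1 maps to alpha1
  expect_equal((sp$beta1 * 1 + sp$beta2 * 0) / sp$a1, 1)
  b <- sample_sphere_inverse(sp, 2000, 5)
  expect_true(all(b$y1 >= sp$beta2 / sp$a1 & b$y1 <= sp$beta1 / sp$a1))
  expect_true(all(b$y2 >= sp$alpha2 & b$y2 <= sp$alpha1))
})

test_that("samplers refuse specs outside their branch", {
  expect_error(sample_sphere_inverse(revolution_half(), 10, 1), "not a sphere")
  expect_error(sample_revolution_inverse(unit_sphere_half(), 10, 1), "sphere")
  expect_error(sample_revolution_inverse(general_patch(), 10, 1), "general")
  expect_error(sample_ar_y1(unit_sphere_half(), 10, 1), "uniform")
  expect_error(sample_ar_y1(general_patch(), 10, 1), "general")
})

test_that("every batch lies on its ellipsoid in all three coordinate systems", {
  batches <- list(
    sample_sphere_inverse(unit_sphere_half(), 500, 2),
    sample_revolution_inverse(revolution_half(), 500, 2),
    sample_revolution_ar(revolution_half(), 500, 2),
    sample_general_ellipsoid(general_patch(), 500, 2))
  for (b in batches) {
    spec <- attr(b, "spec")
    resid <- (b$px / spec$a1)^2 + (b$py / spec$a2)^2 + (b$pz / spec$a3)^2 - 1
    expect_lt(max(abs(resid)), 1e-10)
    # x and y columns are consistent images of each other
    x <- map_g_inverse(spec, b$y1, b$y2)
    expect_equal(b$x1, x$x1, tolerance = 1e-12)
    expect_equal(b$x2, x$x2, tolerance = 1e-12)
    expect_true(all(b$pz >= 0))
  }
})

test_that("fixed seeds give bit-identical batches", {
  expect_identical(sample_sphere_inverse(unit_sphere_half(), 100, 9),
                   sample_sphere_inverse(unit_sphere_half(), 100, 9))
  expect_identical(sample_revolution_inverse(revolution_half(), 100, 9),
                   sample_revolution_inverse(revolution_half(), 100, 9))
  expect_identical(sample_revolution_ar(revolution_half(), 100, 9)$y1,
                   sample_revolution_ar(revolution_half(), 100, 9)$y1)
  expect_identical(sample_general_ellipsoid(general_patch(), 100, 9)$y1,
                   sample_general_ellipsoid(general_patch(), 100, 9)$y1)
  expect_false(identical(sample_sphere_inverse(unit_sphere_half(), 100, 9)$y1,
                         sample_sphere_inverse(unit_sphere_half(), 100, 10)$y1))
})

test_that("semicircular endpoints are reproduced through the interpolant", {
  rev <- revolution_b1()
  sd1 <- sqrt(rev$delta1)
  r1 <- sd1 * rev$beta1 / rev$a1; r2 <- sd1 * rev$beta2 / rev$a1
  tr <- build_phi_inverse(200)
  # U = 0 -> Z = r2, U = 1 -> Z = r1, to interpolant tolerance
  expect_equal(tr$fun(phi(r2, 1)), r2, tolerance = 1e-6)
  expect_equal(tr$fun(phi(r1, 1)), r1, tolerance = 1e-6)
})

test_that("acceptance-rejection matches its envelope analysis", {
  rev <- revolution_b1()
  ar <- sample_ar_y1(rev, 20000, 3)
  lo <- rev$beta2 / rev$a1; hi <- rev$beta1 / rev$a1
  expect_length(ar$samples, 20000)
  expect_true(all(ar$samples >= lo & ar$samples <= hi))
  st <- ar$stats
  expect_lte(st$n_accepted, st$n_proposed)
  # f* is the density maximum at 0 for an origin-containing interval
  sd1 <- sqrt(rev$delta1)
  norm <- (phi(sd1 * hi, 1) - phi(sd1 * lo, 1)) / sd1
  expect_equal(st$f_star, 1 / norm)
  expect_equal(st$c, (hi - lo) / norm)
  # 99% binomial CI for the acceptance rate around 1/c
  p <- 1 / st$c
  half <- 2.576 * sqrt(p * (1 - p) / st$n_proposed)
  expect_lt(abs(st$acceptance_rate - p), half + 1e-12)
})

test_that("inverse-transform marginals match their analytic CDFs", {
  sp <- unit_sphere_octant()
  b <- sample_sphere_inverse(sp, 20000, 17)
  expect_gt(ks_p(b$y1, "punif"), 0.001)
  cdf_y2 <- function(y) (asin(y) - asin(sp$alpha2)) /
    (asin(sp$alpha1) - asin(sp$alpha2))
  expect_gt(ks_p(b$y2, cdf_y2), 0.001)

  rev <- revolution_b1()
  br <- sample_revolution_inverse(rev, 20000, 17)
  sd1 <- sqrt(rev$delta1)
  r1 <- sd1 * rev$beta1 / rev$a1; r2 <- sd1 * rev$beta2 / rev$a1
  cdf_y1 <- function(y) (phi(sd1 * y, 1) - phi(r2, 1)) / (phi(r1, 1) - phi(r2, 1))
  expect_gt(ks_p(br$y1, cdf_y1), 0.001)
})

test_that("Hastings accepts everything on a constant target and targets the box", {
  cfg <- hastings_config(proposal_step = c(0.1, 0.1), burn_in = 100,
                         x0 = c(0.5, 0.5), seed = 8)
  box <- function(y) if (all(y > 0 & y < 1)) 0 else -Inf
  res <- hastings_chain(box, cfg, 2000)
  expect_true(all(res$samples > 0 & res$samples < 1))
  # within the box every proposal is accepted (rho = 1); the only
  # rejections are out-of-box proposals
  inside <- res$samples
  expect_gt(res$acceptance_rate, 0.5)
  # uniform marginals on the box
  expect_gt(ks_p(inside[seq(1, 2000, by = 10), 1], "punif"), 0.001)
})

test_that("Hastings start point must have positive density", {
  cfg <- hastings_config(proposal_step = c(0.1, 0.1), x0 = c(5, 5), seed = 1)
  box <- function(y) if (all(y > 0 & y < 1)) 0 else -Inf
  expect_error(hastings_chain(box, cfg, 10), "zero target density")
})

test_that("uniformity chi-square has its closed-form degenerate values", {
  sp <- unit_sphere_octant()
  bins <- equal_area_bins(sp, 2, 2)
  # perfectly proportional counts -> statistic 0, p = 1
  n_cell <- 50
  pts <- NULL
  for (i in 1:2) for (j in 1:2) {
    y1 <- rep(mean(bins$y1_edges[i:(i + 1)]), n_cell)
    y2 <- rep(mean(bins$y2_edges[j:(j + 1)]), n_cell)
    pts <- rbind(pts, cbind(y1, y2))
  }
  batch <- tibble::tibble(y1 = pts[, 1], y2 = pts[, 2])
  r <- uniformity_chi_square(batch, sp, bins = bins)
  # bins are equal-area to grid accuracy; statistic is near 0, not exactly
  expect_lt(r$statistic, 1e-3)
  # all mass in one of k equal-area cells -> statistic ~ n (k - 1)
  batch1 <- tibble::tibble(y1 = rep(batch$y1[1], 200), y2 = rep(batch$y2[1], 200))
  bins_eq <- bins; bins_eq$areas[] <- mean(bins$areas)  # exactly equal areas
  r1 <- uniformity_chi_square(batch1, sp, bins = bins_eq)
  expect_equal(r1$statistic, 200 * 3)
  expect_equal(r1$p_value, 0)
})

test_that("uniformity chi-square guards its preconditions", {
  sp <- unit_sphere_octant()
  b <- sample_sphere_inverse(sp, 300, 1)
  expect_error(uniformity_chi_square(b, sp, k_bins = 50), "n >= 10")
})

test_that("sample_patch dispatches on the spec shape", {
  expect_equal(sample_patch(unit_sphere_half(), 10, 1)$method[1],
               "sphere_inverse")
  expect_equal(sample_patch(revolution_half(), 10, 1)$method[1],
               "revolution_inverse")
  expect_equal(sample_patch(general_patch(), 10, 1)$method[1], "hastings")
  expect_error(sample_patch(unit_sphere_half(), 10, 1,
                            method = "revolution_inverse"), "sphere")
})
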