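test_that("trilinear interpolation is exact at voxel centers and cell centers", {
  vol <- voxel_volume(array(0:7, dim = c(2, 2, 2)))
  expect_equal(trilinear_sample(vol, c(0.5, 0.5, 0.5)), 3.5)  # corner mean
  set.seed(4)
  vals <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  v <- voxel_volume(vals, spacing = c(0.5, 1, 2), origin = c(-1, 3, 7))
  for (k in 1:20) {
    idx <- c(sample(0:3, 1), sample(0:4, 1), sample(0:5, 1))
    p <- v$origin + idx * v$spacing
    expect_equal(trilinear_sample(v, p), vals[idx[1] + 1, idx[2] + 1, idx[3] + 1])
  }
})

test_that("trilinear interpolation is exact on affine gray fields", {
  d <- c(8, 9, 10)
  f <- function(x, y, z) 2 * x - 3 * y + z + 5
  vals <- array(0, dim = d)
  for (k in 0:(d[3] - 1))
    vals[, , k + 1] <- outer(2 * (0:(d[1] - 1)), -3 * (0:(d[2] - 1)), `+`) + k + 5
  vol <- voxel_volume(vals)
  set.seed(8)
  pts <- tibble::tibble(px = runif(1000, 0, d[1] - 1),
                        py = runif(1000, 0, d[2] - 1),
                        pz = runif(1000, 0, d[3] - 1))
  tc <- texture_points(pts, vol)
  expect_true(all(tc$inside))
  expect_lt(max(abs(tc$gray - f(pts$px, pts$py, pts$pz))), 1e-10)
})

test_that("trilinear output is bounded by the enclosing cell's corners", {
  set.seed(5)
  vals <- array(runif(27), dim = c(3, 3, 3))
  vol <- voxel_volume(vals)
  pts <- tibble::tibble(px = runif(500, 0, 2), py = runif(500, 0, 2),
                        pz = runif(500, 0, 2))
  tc <- texture_points(pts, vol)
  for (k in seq_len(500)) {
    i <- pmin(floor(c(pts$px[k], pts$py[k], pts$pz[k])), 1)
    cell <- vals[i[1] + 1:2, i[2] + 1:2, i[3] + 1:2]
    expect_gte(tc$gray[k], min(cell) - 1e-12)
    expect_lte(tc$gray[k], max(cell) + 1e-12)
  }
})

test_that("out-of-box points are flagged, never dropped", {
  vol <- voxel_volume(array(1, dim = c(3, 3, 3)))
  pts <- tibble::tibble(px = c(1, -5, 1), py = c(1, 1, 10), pz = c(1, 1, 1))
  tc <- texture_points(pts, vol)
  expect_equal(nrow(tc), 3)
  expect_equal(tc$inside, c(TRUE, FALSE, FALSE))
  expect_true(is.na(tc$gray[2]) && is.na(tc$gray[3]))
  expect_error(trilinear_sample(vol, c(-5, 1, 1)), "outside")
  empty <- texture_points(tibble::tibble(px = numeric(), py = numeric(),
                                         pz = numeric()), vol)
  expect_equal(nrow(empty), 0)
})

test_that("sphere fit recovers exact data exactly and is translation equivariant", {
  pts <- noisy_sphere_points(c(1, 2, 3), 7, 50, sigma = 0, seed = 6)
  fit <- fit_sphere_lsq(pts)
  expect_equal(fit$center, c(1, 2, 3), tolerance = 1e-10)
  expect_equal(fit$semiaxes, rep(7, 3), tolerance = 1e-10)
  shifted <- dplyr::mutate(pts, px = px + 10, py = py - 4, pz = pz + 0.5)
  fit2 <- fit_sphere_lsq(shifted)
  expect_equal(fit2$center, fit$center + c(10, -4, 0.5), tolerance = 1e-10)
  expect_equal(fit2$semiaxes, fit$semiaxes, tolerance = 1e-10)
})

test_that("sphere fit rejects degenerate configurations", {
  flat <- tibble::tibble(px = runif(10), py = runif(10), pz = 0)
  expect_error(fit_sphere_lsq(flat), "degenerate|coplanar")
  expect_error(fit_sphere_lsq(flat[1:3, ]), "at least 4")
})

test_that("noisy sphere recovery is within the observed Monte-Carlo spread", {
  errs <- sapply(1:10, function(s) {
    pts <- noisy_sphere_points(c(10, 20, 30), 25, 500, sigma = 0.5, seed = s)
    fit <- fit_sphere_lsq(pts)
    c(center = sqrt(sum((fit$center - c(10, 20, 30))^2)),
      radius = abs(fit$semiaxes[1] - 25))
  })
  expect_lt(mean(errs["center", ]), 0.1)
  expect_lt(mean(errs["radius", ]), 0.1)
})

test_that("revolution fit recovers exact spheroids and nests the sphere", {
  pts <- noisy_spheroid_points(c(1, 2, 3), 10, 6, axis = c(0, 1, 0),
                               n = 200, sigma = 0, seed = 4)
  fit <- fit_ellipsoid_revolution_lsq(pts, axis = c(0, 1, 0))
  expect_equal(fit$center, c(1, 2, 3), tolerance = 1e-8)
  expect_equal(fit$semiaxes, c(10, 6, 6), tolerance = 1e-8)
  # sphere input: reduces to the sphere fit within noise tolerance
  sph <- noisy_sphere_points(c(5, 5, 5), 12, 800, sigma = 0.2, seed = 9)
  fr <- fit_ellipsoid_revolution_lsq(sph, axis = c(0, 0, 1))
  fs <- fit_sphere_lsq(sph)
  expect_lt(max(abs(fr$semiaxes - fs$semiaxes)), 0.1)
  expect_lt(sqrt(sum((fr$center - fs$center)^2)), 0.1)
})

test_that("noisy spheroid recovery is within the observed Monte-Carlo spread", {
  errs <- sapply(1:10, function(s) {
    pts <- noisy_spheroid_points(c(5, 5, 5), 25, 20, axis = c(0, 0, 1),
                                 n = 1000, sigma = 0.5, seed = s)
    fit <- fit_ellipsoid_revolution_lsq(pts, axis = c(0, 0, 1))
    max(abs(fit$semiaxes - c(25, 20, 20)))
  })
  expect_lt(mean(errs), 0.2)
})

test_that("fit error shrinks as the noise shrinks", {
  mean_err <- function(sigma) {
    mean(sapply(1:10, function(s) {
      pts <- noisy_sphere_points(c(0, 0, 0), 25, 500, sigma = sigma, seed = s)
      fit <- fit_sphere_lsq(pts)
      sqrt(sum((fit$center)^2)) + abs(fit$semiaxes[1] - 25)
    }))
  }
  errs <- vapply(c(0.5, 0.05, 0.005), mean_err, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("revolution fit is equivariant under rotation about its axis", {
  pts <- noisy_spheroid_points(c(0, 0, 0), 10, 6, axis = c(0, 0, 1),
                               n = 300, sigma = 0, seed = 11)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  M <- as.matrix(pts) %*% t(R)
  rot <- tibble::tibble(px = M[, 1], py = M[, 2], pz = M[, 3])
  f1 <- fit_ellipsoid_revolution_lsq(pts, axis = c(0, 0, 1))
  f2 <- fit_ellipsoid_revolution_lsq(rot, axis = c(0, 0, 1))
  expect_equal(f2$semiaxes, f1$semiaxes, tolerance = 1e-8)
  expect_equal(f2$center, as.numeric(R %*% f1$center), tolerance = 1e-8)
})

test_that("tidy and glance expose the fitted parameters", {
  pts <- noisy_sphere_points(c(1, 1, 1), 5, 100, sigma = 0, seed = 2)
  fit <- fit_sphere_lsq(pts)
  td <- tidy(fit)
  expect_equal(td$term, c("center_x", "center_y", "center_z", "a1", "a2", "a3"))
  expect_equal(td$estimate[4], 5, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$kind, "sphere")
  expect_equal(gl$radius, 5, tolerance = 1e-10)
})

test_that("patch_from_fit places a sphere patch that lies on the fitted sphere", {
  pts <- noisy_sphere_points(c(32, 32, 32), 12, 500, sigma = 0, seed = 5)
  fit <- fit_sphere_lsq(pts)
  pl <- patch_from_fit(fit)
  b <- sample_sphere_inverse(pl$spec, 200, 3)
  w <- to_world(b, pl)
  r <- sqrt((w$px - 32)^2 + (w$py - 32)^2 + (w$pz - 32)^2)
  expect_lt(max(abs(r - 12)), 1e-8)
})
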