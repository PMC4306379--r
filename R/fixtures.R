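# Synthetic inputs: a shoulder-like phantom volume (humeral head with a
# bright tendon-footprint shell carrying a darker "partial tear" cap) and
# noisy quadric point clouds for the fitting routines. Everything is a pure
# function of its specification and seed.

#' Specification of the synthetic shoulder phantom
#'
#' The phantom emulates the geometry a curved-surface view of the rotator
#' cuff has to resolve: a spherical humeral head whose surface carries a
#' bright shell (the tendon footprint) with a darker spherical-cap defect
#' (the partial tear). Default intensities are well separated
#' (background 20, shell 200, tear 60, noise sd 5) so threshold-free
#' fraction checks are stable; the default grid (128^3 at 1 mm) keeps a
#' 50,000-point texture near unit-voxel sampling density.
#'
#' @param dims Grid extents (length 3).
#' @param spacing Voxel size per axis (mm).
#' @param head_center Center of the humeral-head sphere (mm, world).
#' @param head_radius Head radius (mm).
#' @param shell_thickness Radial thickness of the bright shell (mm); the
#'   shell straddles the head radius symmetrically.
#' @param shell_intensity,background_intensity,tear_intensity Gray levels.
#' @param tear_center_angles Direction of the tear cap center as
#'   `(azimuth, elevation)` in radians (elevation measured from the equator).
#' @param tear_angular_radius Angular radius of the tear cap (radians, in
#'   `(0, pi/2)`).
#' @param noise_sigma Additive Gaussian noise standard deviation (gray).
#' @param seed Integer noise seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(128, 128, 128), spacing = c(1, 1, 1),
                         head_center = c(64, 64, 64), head_radius = 24,
                         shell_thickness = 4, shell_intensity = 200,
                         background_intensity = 20, tear_intensity = 60,
                         tear_center_angles = c(0.6, 0.9),
                         tear_angular_radius = 0.4,
                         noise_sigma = 5, seed = 1L) {
  stopifnot(head_radius > shell_thickness, shell_thickness > 0,
            tear_angular_radius > 0, tear_angular_radius < pi / 2,
            noise_sigma >= 0, all(dims >= 2), all(spacing > 0))
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 head_center = as.numeric(head_center),
                 head_radius = head_radius, shell_thickness = shell_thickness,
                 shell_intensity = shell_intensity,
                 background_intensity = background_intensity,
                 tear_intensity = tear_intensity,
                 tear_center_angles = as.numeric(tear_center_angles),
                 tear_angular_radius = tear_angular_radius,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# unit vector for (azimuth, elevation)
direction_from_angles <- function(az, el) {
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

#' Generate the synthetic shoulder phantom volume
#'
#' Voxels within `shell_thickness / 2` of the head sphere get
#' `shell_intensity`; within the shell, voxels whose direction from the head
#' center lies within `tear_angular_radius` of the tear direction get
#' `tear_intensity`; everything else is background. Regions are
#' set-exclusive before the seeded Gaussian noise is added.
#'
#' @param spec A [phantom_spec()].
#' @return A [voxel_volume()].
#' @export
synthetic_shoulder_volume <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  extent_lo <- numeric(3); extent_hi <- numeric(3)
  for (ax in 1:3) {
    extent_lo[ax] <- spec$head_center[ax] - spec$head_radius - spec$shell_thickness
    extent_hi[ax] <- spec$head_center[ax] + spec$head_radius + spec$shell_thickness
  }
  world_max <- (d - 1) * spec$spacing  # origin fixed at 0
  if (any(extent_lo < 0) || any(extent_hi > world_max))
    stop("phantom sphere plus shell does not fit inside the volume", call. = FALSE)
  xs <- (0:(d[1] - 1)) * spec$spacing[1] - spec$head_center[1]
  ys <- (0:(d[2] - 1)) * spec$spacing[2] - spec$head_center[2]
  zs <- (0:(d[3] - 1)) * spec$spacing[3] - spec$head_center[3]
  X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)
  r <- sqrt(X^2 + Y^2 + Z^2)
  shell <- abs(r - spec$head_radius) <= spec$shell_thickness / 2
  dir <- direction_from_angles(spec$tear_center_angles[1],
                               spec$tear_center_angles[2])
  cosang <- (X * dir[1] + Y * dir[2] + Z * dir[3]) / pmax(r, 1e-9)
  tear <- shell & cosang >= cos(spec$tear_angular_radius)
  vals <- array(spec$background_intensity, dim = d)
  vals[shell] <- spec$shell_intensity
  vals[tear] <- spec$tear_intensity
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    vals <- vals + array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d)
  }
  voxel_volume(vals, spacing = spec$spacing, origin = c(0, 0, 0))
}

#' Designed area fraction of the phantom tear cap
#'
#' The tear is a spherical cap of angular radius \eqn{\theta}; its area is
#' \eqn{2\pi r^2 (1-\cos\theta)}, i.e. a fraction \eqn{1-\cos\theta} of the
#' upper hemisphere (\eqn{(1-\cos\theta)/2} of the full sphere).
#'
#' @param spec A [phantom_spec()].
#' @param of One of `"hemisphere"` or `"sphere"`.
#' @return The designed fraction (dimensionless).
#' @export
tear_cap_fraction <- function(spec, of = c("hemisphere", "sphere")) {
  of <- match.arg(of)
  f <- 1 - cos(spec$tear_angular_radius)
  if (of == "sphere") f / 2 else f
}

#' Noisy points on a sphere
#'
#' Uniform directions (normalized isotropic Gaussians) at the given radius
#' plus radial Gaussian noise; input for the least-squares fitting routines.
#'
#' @param center Sphere center (length-3, mm).
#' @param radius Sphere radius (mm, > 0).
#' @param n Number of points (>= 4).
#' @param sigma Radial noise standard deviation (mm, >= 0).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `px`, `py`, `pz`.
#' @export
noisy_sphere_points <- function(center, radius, n, sigma = 0, seed = 1L) {
  stopifnot(n >= 4, radius > 0, sigma >= 0, length(center) == 3)
  set.seed(as.integer(seed))
  G <- matrix(stats::rnorm(3 * n), ncol = 3)
  G <- G / sqrt(rowSums(G^2))
  r <- radius + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  tibble::tibble(px = center[1] + r * G[, 1],
                 py = center[2] + r * G[, 2],
                 pz = center[3] + r * G[, 3])
}

#' Noisy points on an ellipsoid of revolution
#'
#' Surface-uniform points on the full spheroid with symmetry axis `axis`
#' (semiaxis `a_axis` along it, `a_trans` transverse), plus noise along the
#' outward surface normal; input for [fit_ellipsoid_revolution_lsq()].
#'
#' @param center Ellipsoid center (mm).
#' @param a_axis,a_trans Semiaxes along / transverse to the symmetry axis.
#' @param axis Symmetry-axis direction.
#' @param n Number of points (>= 6).
#' @param sigma Normal-direction noise sd (mm).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `px`, `py`, `pz`.
#' @export
noisy_spheroid_points <- function(center, a_axis, a_trans, axis = c(0, 0, 1),
                                  n, sigma = 0, seed = 1L) {
  stopifnot(n >= 6, a_axis > 0, a_trans > 0, sigma >= 0)
  set.seed(as.integer(seed))
  # surface-uniform via rejection from the sphere parametrization
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    m <- 2 * (n - nrow(pts)) + 16
    G <- matrix(stats::rnorm(3 * m), ncol = 3)
    G <- G / sqrt(rowSums(G^2))
    S <- cbind(a_trans * G[, 1], a_trans * G[, 2], a_axis * G[, 3])
    # area element ratio for anisotropic scaling of the unit sphere
    nrm <- cbind(S[, 1] / a_trans^2, S[, 2] / a_trans^2, S[, 3] / a_axis^2)
    dens <- sqrt(rowSums(nrm^2)) * a_trans^2 * a_axis
    keep <- stats::runif(m) <= dens / max(dens)
    pts <- rbind(pts, S[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  if (sigma > 0) {
    nrm <- cbind(pts[, 1] / a_trans^2, pts[, 2] / a_trans^2, pts[, 3] / a_axis^2)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    pts <- pts + nrm * stats::rnorm(n, 0, sigma)
  }
  # rotate local (u, v, axis) coords into world: world = u*Fr1 + v*Fr2 + t*Fr3
  Fr <- axis_frame(axis)           # columns u, v, axis
  W <- pts %*% t(Fr)
  tibble::tibble(px = W[, 1] + center[1], py = W[, 2] + center[2],
                 pz = W[, 3] + center[3])
}

#' Serialize a phantom specification
#'
#' Flat `key = value` text, matching the patch-config dialect.
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @export
write_phantom_config <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  lines <- c(sprintf("dims = %s", paste(spec$dims, collapse = ",")),
             sprintf("spacing = %s", num(spec$spacing)),
             sprintf("head_center = %s", num(spec$head_center)),
             sprintf("head_radius = %.17g", spec$head_radius),
             sprintf("shell_thickness = %.17g", spec$shell_thickness),
             sprintf("shell_intensity = %.17g", spec$shell_intensity),
             sprintf("background_intensity = %.17g", spec$background_intensity),
             sprintf("tear_intensity = %.17g", spec$tear_intensity),
             sprintf("tear_center_angles = %s", num(spec$tear_center_angles)),
             sprintf("tear_angular_radius = %.17g", spec$tear_angular_radius),
             sprintf("noise_sigma = %.17g", spec$noise_sigma),
             sprintf("seed = %d", spec$seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  kv <- parse_flat_config(path)
  splitnum <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  phantom_spec(dims = splitnum(kv[["dims"]]),
               spacing = splitnum(kv[["spacing"]]),
               head_center = splitnum(kv[["head_center"]]),
               head_radius = as.numeric(kv[["head_radius"]]),
               shell_thickness = as.numeric(kv[["shell_thickness"]]),
               shell_intensity = as.numeric(kv[["shell_intensity"]]),
               background_intensity = as.numeric(kv[["background_intensity"]]),
               tear_intensity = as.numeric(kv[["tear_intensity"]]),
               tear_center_angles = splitnum(kv[["tear_center_angles"]]),
               tear_angular_radius = as.numeric(kv[["tear_angular_radius"]]),
               noise_sigma = as.numeric(kv[["noise_sigma"]]),
               seed = as.integer(kv[["seed"]]))
}
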