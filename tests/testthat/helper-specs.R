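# shared fixtures: canonical patch specifications and small helpers

unit_sphere_half <- function() ellipsoid_patch(1, 1, 1)
unit_sphere_octant <- function()
  ellipsoid_patch(1, 1, 1, alpha1 = 1, alpha2 = 0, beta1 = 1, beta2 = 0)
revolution_half <- function() ellipsoid_patch(2, 1, 1)  # beta = (-2, 2)
revolution_b1 <- function()
  ellipsoid_patch(2, 1, 1, beta1 = 1, beta2 = -1)
general_patch <- function()
  ellipsoid_patch(3, 2, 1, alpha1 = 0.9, alpha2 = -0.9,
                  beta1 = 2.7, beta2 = -2.7)

# small noiseless phantom for fast texturing tests
small_phantom_spec <- function(noise_sigma = 0)
  phantom_spec(dims = c(64, 64, 64), head_center = c(32, 32, 32),
               head_radius = 12, shell_thickness = 3,
               noise_sigma = noise_sigma)

# quiet KS wrappers (ties from thinned MCMC repeats trigger harmless warnings)
ks_p <- function(x, y, ...) suppressWarnings(stats::ks.test(x, y, ...)$p.value)

# random rational degree-4 patch with positive weights
random_patch <- function(seed) {
  set.seed(seed)
  mi <- subset(expand.grid(i1 = 0:4, i2 = 0:4), i1 + i2 <= 4)
  bezier_patch(tibble::tibble(
    i1 = mi$i1, i2 = mi$i2, i3 = 4 - mi$i1 - mi$i2,
    x = rnorm(15), y = rnorm(15), z = rnorm(15),
    w = runif(15, 0.2, 3)))
}

# random interior barycentric coordinates
random_barycentric <- function(n, seed) {
  set.seed(seed)
  g <- matrix(-log(runif(3 * n)), ncol = 3)
  g / rowSums(g)
}
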