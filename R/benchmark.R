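# Benchmark harness comparing the cost of generating n patch points by each
# applicable method. Timings are reported, never asserted: they depend on
# the machine. The table shape matches the classical comparison: 3 methods
# for the sphere octant (inverse transform, Bernstein, de Casteljau), 5 for
# the ellipsoid-of-revolution octant (the phi-inverse approximation,
# acceptance-rejection, Hastings, Bernstein, de Casteljau).

octant_spec <- function(kind = c("sphere", "revolution"), a1 = 2) {
  kind <- match.arg(kind)
  if (kind == "sphere")
    ellipsoid_patch(1, 1, 1, alpha1 = 1, alpha2 = 0, beta1 = 1, beta2 = 0)
  else
    ellipsoid_patch(a1, 1, 1, alpha1 = 1, alpha2 = 0, beta1 = a1, beta2 = 0)
}

median_time <- function(fn, repeats, warmup = 1) {
  for (i in seq_len(warmup)) fn()
  stats::median(vapply(seq_len(repeats),
                       function(i) system.time(fn())[["elapsed"]],
                       numeric(1)))
}

#' Benchmark patch evaluation methods
#'
#' Times every applicable point-generation method on the sphere or
#' ellipsoid-of-revolution octant at each requested batch size. Random
#' methods generate `n` surface points; the deterministic evaluators run on
#' the first `n` lattice parameters (the largest triangular lattice that
#' fits, padded with leading points of the next finer one, since benchmark
#' sizes need not be triangular numbers). Each cell is the median of
#' `repeats` runs after one warm-up.
#'
#' @param kind `"sphere"` or `"revolution"`.
#' @param n Batch sizes (default the classical `c(1035, 10011, 50086)`).
#' @param repeats Repetitions per cell (median is reported).
#' @param seed Base RNG seed for the random methods.
#' @return A tibble with columns `method`, `n`, `seconds`.
#' @export
benchmark_evaluators <- function(kind = c("sphere", "revolution"),
                                 n = c(1035, 10011, 50086),
                                 repeats = 7, seed = 1L) {
  kind <- match.arg(kind)
  spec <- octant_spec(kind)
  patch <- if (kind == "sphere") sphere_octant_patch(1)
           else ellipsoid_octant_patch(spec$a1, spec$a2, spec$a3)
  transform <- if (kind == "revolution") build_phi_inverse() else NULL
  methods <- if (kind == "sphere")
    list(inverse_transform = function(k) sample_sphere_inverse(spec, k, seed),
         bernstein = function(k) bernstein_eval(patch, barycentric_points_n(k)),
         de_casteljau = function(k) de_casteljau(patch, barycentric_points_n(k)))
  else
    list(phi_inverse = function(k)
           sample_revolution_inverse(spec, k, seed, transform),
         acceptance_rejection = function(k) sample_revolution_ar(spec, k, seed),
         hastings = function(k) sample_general_ellipsoid(spec, k, seed),
         bernstein = function(k) bernstein_eval(patch, barycentric_points_n(k)),
         de_casteljau = function(k) de_casteljau(patch, barycentric_points_n(k)))
  grid <- expand.grid(method = names(methods), n = n,
                      stringsAsFactors = FALSE)
  grid$seconds <- mapply(function(m, k)
    median_time(function() methods[[m]](k), repeats), grid$method, grid$n)
  tibble::as_tibble(grid)
}
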