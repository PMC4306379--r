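# Surface-uniform random samplers. Each sampler draws the rectangle vector Y
# on D_g, pulls back to the planar domain through g^{-1}, and lifts to the
# surface. Batches are tibbles carrying all three coordinate systems at once.
#
# Reproducibility contract: each sampler seeds base R's RNG once with the
# given seed; uniforms are drawn per point in the order U1 then U2. A fixed
# seed therefore yields a bit-identical batch.

new_sample_batch <- function(method, seed, spec, y1, y2, extra = list()) {
  x <- map_g_inverse(spec, y1, y2)
  p <- surface_point(spec, x$x1, x$x2)
  out <- tibble::tibble(method = method, seed = as.integer(seed),
                        y1 = y1, y2 = y2, x1 = x$x1, x2 = x$x2,
                        px = p$px, py = p$py, pz = p$pz)
  attr(out, "spec") <- spec
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("sample_batch", class(out))
  out
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("<sample_batch> method = %s, n = %d, seed = %d\n",
              x$method[1], nrow(x), x$seed[1]))
  NextMethod()
}

# shared draw of the y2 coordinate (identical for sphere and revolution):
# y2 = sin(U * asin(alpha1) + (1 - U) * asin(alpha2))
draw_y2 <- function(spec, u) {
  sin(u * asin(spec$alpha1) + (1 - u) * asin(spec$alpha2))
}

#' Inverse-transform sampler for a spherical patch
#'
#' On a sphere the rectangle coordinates are independent with
#' \eqn{Y_1} uniform on \eqn{(\beta_2/a_1, \beta_1/a_1)} and
#' \eqn{Y_2 = \sin(U \arcsin\alpha_1 + (1-U)\arcsin\alpha_2)}, so both
#' marginals invert in closed form.
#'
#' @param spec An [ellipsoid_patch()] with `is_sphere = TRUE`.
#' @param n Number of points.
#' @param seed Integer RNG seed.
#' @return A `sample_batch` tibble with columns `method`, `seed`, `y1`, `y2`,
#'   `x1`, `x2`, `px`, `py`, `pz`.
#' @export
sample_sphere_inverse <- function(spec, n, seed) {
  stopifnot(inherits(spec, "ellipsoid_patch"), n >= 1)
  if (!spec$is_sphere)
    stop("spec is not a sphere; use sample_revolution_inverse() or ",
         "sample_general_ellipsoid()", call. = FALSE)
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(2 * n), ncol = 2, byrow = TRUE)  # per point: U1, U2
  y1 <- (spec$beta1 * u[, 1] + spec$beta2 * (1 - u[, 1])) / spec$a1
  y2 <- draw_y2(spec, u[, 2])
  new_sample_batch("sphere_inverse", seed, spec, y1, y2)
}

#' Inverse-transform sampler for an ellipsoid-of-revolution patch
#'
#' The \eqn{y_2} draw is as on the sphere. The \eqn{y_1} marginal has density
#' proportional to \eqn{\sqrt{1-\delta_1 y_1^2}}; rescaling
#' \eqn{Z = \sqrt{\delta_1} Y_1} gives the semicircular law on
#' \eqn{(r_2, r_1)}, \eqn{r_i = \sqrt{\delta_1}\,\beta_i/a_1}, sampled by
#' \eqn{Z = \phi^{-1}(U\phi(r_1;1) + (1-U)\phi(r_2;1);\,1)} through the
#' tabulated inverse.
#'
#' @param spec An [ellipsoid_patch()] with `is_revolution = TRUE`.
#' @param n Number of points.
#' @param seed Integer RNG seed.
#' @param transform A [build_phi_inverse()] object (built at default accuracy
#'   when omitted).
#' @return A `sample_batch` tibble.
#' @export
sample_revolution_inverse <- function(spec, n, seed, transform = NULL) {
  stopifnot(inherits(spec, "ellipsoid_patch"), n >= 1)
  if (spec$is_sphere)
    stop("spec is a sphere; use sample_sphere_inverse()", call. = FALSE)
  if (!spec$is_revolution)
    stop("spec is a general ellipsoid; use sample_general_ellipsoid()",
         call. = FALSE)
  if (is.null(transform)) transform <- build_phi_inverse()
  stopifnot(inherits(transform, "semicircular_transform"))
  sd1 <- sqrt(spec$delta1)
  r1 <- sd1 * spec$beta1 / spec$a1
  r2 <- sd1 * spec$beta2 / spec$a1
  pr <- phi(c(r2, r1), 1)
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(2 * n), ncol = 2, byrow = TRUE)
  z <- pmin(r1, pmax(r2, transform$fun(u[, 1] * pr[2] + (1 - u[, 1]) * pr[1])))
  y1 <- z / sd1
  y2 <- draw_y2(spec, u[, 2])
  new_sample_batch("revolution_inverse", seed, spec, y1, y2,
                   extra = list(transform_knots = transform$n_knots))
}

#' Acceptance-rejection sampler for the y1 marginal
#'
#' Draws from the density proportional to \eqn{\sqrt{1-\delta_1 y_1^2}} on
#' \eqn{(\beta_2/a_1, \beta_1/a_1)} using the uniform envelope on that
#' interval. The envelope constant is \eqn{c = ((\beta_1-\beta_2)/a_1) f^*}
#' with \eqn{f^*} the maximum of the normalized marginal density: its value at
#' 0 if 0 lies in the interval, else the larger endpoint value. Proposals are
#' accepted with probability \eqn{f(x)/(c\,g(x))}; the method's efficiency is
#' \eqn{1/c}.
#'
#' @param spec An [ellipsoid_patch()] with `is_revolution = TRUE`.
#' @param n Number of accepted samples to return (the proposal loop runs
#'   until exactly `n` are accepted).
#' @param seed Integer RNG seed.
#' @return A list with `samples` (length-`n` numeric vector of y1 draws) and
#'   `stats`, a one-row tibble with columns `c`, `f_star`, `n_proposed`,
#'   `n_accepted`, `acceptance_rate`.
#' @export
sample_ar_y1 <- function(spec, n, seed) {
  stopifnot(inherits(spec, "ellipsoid_patch"), n >= 1)
  if (!spec$is_revolution)
    stop(if (spec$is_sphere)
      "spec is a sphere: the y1 marginal is uniform (c = 1), no rejection needed"
      else "spec is a general ellipsoid; use sample_general_ellipsoid()",
      call. = FALSE)
  lo <- spec$beta2 / spec$a1; hi <- spec$beta1 / spec$a1
  d1 <- spec$delta1; sd1 <- sqrt(d1)
  # normalized marginal: f_g1(y) = sqrt(1 - d1 y^2) * sd1 / (phi(r1;1) - phi(r2;1))
  norm <- (phi(sd1 * hi, 1) - phi(sd1 * lo, 1)) / sd1
  fg1 <- function(y) sqrt(1 - d1 * y^2) / norm
  f_star <- if (lo < 0 && hi > 0) fg1(0) else max(fg1(lo), fg1(hi))
  cc <- (hi - lo) * f_star
  set.seed(as.integer(seed))
  samples <- numeric(0)
  n_proposed <- 0L
  while (length(samples) < n) {
    chunk <- max(1024L, ceiling((n - length(samples)) * cc * 1.2))
    x <- stats::runif(chunk, lo, hi)
    u <- stats::runif(chunk)
    keep <- u <= fg1(x) / f_star   # = f/(c g) with the uniform envelope
    n_proposed <- n_proposed + chunk
    samples <- c(samples, x[keep])
  }
  list(samples = samples[seq_len(n)],
       stats = tibble::tibble(c = cc, f_star = f_star,
                              n_proposed = n_proposed,
                              n_accepted = length(samples),
                              acceptance_rate = length(samples) / n_proposed))
}

#' Full-batch acceptance-rejection sampler (revolution patch)
#'
#' Combines [sample_ar_y1()] for the \eqn{y_1} coordinate with the closed-form
#' inverse transform for \eqn{y_2} (the coordinates are independent on an
#' ellipsoid of revolution).
#'
#' @inheritParams sample_revolution_inverse
#' @return A `sample_batch` tibble with the acceptance statistics attached as
#'   attribute `ar_stats`.
#' @export
sample_revolution_ar <- function(spec, n, seed) {
  ar <- sample_ar_y1(spec, n, seed)
  y2 <- draw_y2(spec, stats::runif(n))  # continues the same seeded stream
  new_sample_batch("acceptance_rejection", seed, spec, ar$samples, y2,
                   extra = list(ar_stats = ar$stats))
}

#' Configuration for the Hastings sampler
#'
#' @param proposal_step Standard deviations of the Gaussian random-walk
#'   proposal, one per coordinate (default, chosen at run time: 0.25 times
#'   the side lengths of `D_g`).
#' @param burn_in Iterations discarded before recording.
#' @param thin Keep every `thin`-th state after burn-in.
#' @param x0 Starting point in `D_g` (default: rectangle center).
#' @param seed Integer RNG seed.
#' @return An object of class `hastings_config`.
#' @export
hastings_config <- function(proposal_step = NULL, burn_in = 2000L, thin = 1L,
                            x0 = NULL, seed = 1L) {
  stopifnot(burn_in >= 0, thin >= 1)
  structure(list(proposal_step = proposal_step, burn_in = as.integer(burn_in),
                 thin = as.integer(thin), x0 = x0, seed = as.integer(seed)),
            class = "hastings_config")
}

#' Metropolis-Hastings chain on the rectangle domain
#'
#' Random-walk Hastings sampler for an unnormalized target known through its
#' log density. At step \eqn{t} a proposal \eqn{x'} from \eqn{q(\cdot|x_{t-1})}
#' is accepted with probability
#' \eqn{\rho = \min\{1, \pi(x')q(x_{t-1}|x') / (\pi(x_{t-1})q(x'|x_{t-1}))\}};
#' with the symmetric Gaussian walk used here the \eqn{q} terms cancel.
#' Proposals where the target vanishes (outside the domain) are rejected.
#'
#' @param log_target Function of a length-2 numeric vector returning the
#'   unnormalized log density (`-Inf` outside the support).
#' @param config A [hastings_config()]; `proposal_step` and `x0` must be set.
#' @param n Number of retained (post burn-in, thinned) samples.
#' @return A list with `samples` (an `n` x 2 matrix) and `acceptance_rate`.
#' @export
hastings_chain <- function(log_target, config, n) {
  stopifnot(inherits(config, "hastings_config"), n >= 1,
            !is.null(config$proposal_step), !is.null(config$x0))
  x <- as.numeric(config$x0)
  lt <- log_target(x)
  if (!is.finite(lt)) stop("Hastings start point has zero target density", call. = FALSE)
  step <- rep_len(as.numeric(config$proposal_step), 2L)
  total <- config$burn_in + n * config$thin
  set.seed(config$seed)
  out <- matrix(NA_real_, n, 2)
  kept <- 0L; accepted <- 0L
  for (t in seq_len(total)) {
    prop <- x + stats::rnorm(2L, 0, step)
    lt_prop <- log_target(prop)
    # symmetric q: rho = min(1, pi(x') / pi(x))
    if (is.finite(lt_prop) && log(stats::runif(1)) < lt_prop - lt) {
      x <- prop; lt <- lt_prop; accepted <- accepted + 1L
    }
    if (t > config$burn_in && (t - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- x
    }
  }
  rate <- accepted / total
  if (rate < 0.01 || rate > 0.99)
    warning(sprintf("Hastings acceptance rate %.3f outside (0.01, 0.99); tune proposal_step", rate))
  list(samples = out, acceptance_rate = rate)
}

default_hastings_config <- function(spec, config = NULL, seed = 1L) {
  if (is.null(config)) config <- hastings_config(seed = seed)
  w1 <- (spec$beta1 - spec$beta2) / spec$a1
  w2 <- spec$alpha1 - spec$alpha2
  if (is.null(config$proposal_step)) config$proposal_step <- 0.25 * c(w1, w2)
  if (is.null(config$x0))
    config$x0 <- c((spec$beta1 + spec$beta2) / (2 * spec$a1),
                   (spec$alpha1 + spec$alpha2) / 2)
  config$seed <- as.integer(seed)
  config
}

#' Hastings sampler for a patch on a general ellipsoid
#'
#' For a triaxial ellipsoid the rectangle coordinates are no longer
#' independent and the one-dimensional inverse transforms would require
#' elliptic integrals, so the two-dimensional unnormalized density on
#' \eqn{D_g} is sampled directly with the random-walk Hastings chain. Also
#' valid on sphere and revolution patches (where it must agree in
#' distribution with the specialized samplers).
#'
#' @param spec Any valid [ellipsoid_patch()].
#' @param n Number of retained samples.
#' @param seed Integer RNG seed.
#' @param config Optional [hastings_config()]; unset fields are filled with
#'   the defaults (step 0.25 of each rectangle side, burn-in 2000, thin 1,
#'   start at the rectangle center).
#' @return A `sample_batch` tibble with the realized `acceptance_rate`
#'   attached as an attribute.
#' @export
sample_general_ellipsoid <- function(spec, n, seed, config = NULL) {
  stopifnot(inherits(spec, "ellipsoid_patch"), n >= 1)
  config <- default_hastings_config(spec, config, seed)
  res <- hastings_chain(log_fg_unnormalized(spec), config, n)
  new_sample_batch("hastings", seed, spec, res$samples[, 1], res$samples[, 2],
                   extra = list(acceptance_rate = res$acceptance_rate,
                                hastings_config = config))
}

#' Dispatch a sampler by method tag
#'
#' @param spec An [ellipsoid_patch()].
#' @param n Number of points.
#' @param seed Integer RNG seed.
#' @param method One of `"sphere_inverse"`, `"revolution_inverse"`,
#'   `"acceptance_rejection"`, `"hastings"`, or `"auto"` (fastest applicable:
#'   inverse transform where it exists, Hastings otherwise).
#' @param ... Passed to the selected sampler.
#' @return A `sample_batch` tibble.
#' @export
sample_patch <- function(spec, n, seed,
                         method = c("auto", "sphere_inverse", "revolution_inverse",
                                    "acceptance_rejection", "hastings"), ...) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (spec$is_sphere) "sphere_inverse"
              else if (spec$is_revolution) "revolution_inverse"
              else "hastings"
  switch(method,
         sphere_inverse = sample_sphere_inverse(spec, n, seed),
         revolution_inverse = sample_revolution_inverse(spec, n, seed, ...),
         acceptance_rejection = sample_revolution_ar(spec, n, seed),
         hastings = sample_general_ellipsoid(spec, n, seed, ...))
}

#' @export
glance.sample_batch <- function(x, ...) {
  ar <- attr(x, "ar_stats")
  tibble::tibble(method = x$method[1], n = nrow(x), seed = x$seed[1],
                 acceptance_rate = if (!is.null(ar)) ar$acceptance_rate
                                   else attr(x, "acceptance_rate") %||% NA_real_)
}
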