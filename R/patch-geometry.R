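# Geometry of ellipsoidal surface patches: the planar domain D, the surface
# graph x3(x1, x2), the surface-uniform density f, and the rectangularizing
# change of variables g taking D to the rectangle D_g.

#' Define an ellipsoidal surface patch
#'
#' A patch on the upper half of the ellipsoid
#' \eqn{(x_1/a_1)^2 + (x_2/a_2)^2 + (x_3/a_3)^2 = 1} (with
#' \eqn{a_1 \ge a_2 \ge a_3 > 0}), given as the graph of
#' \eqn{x_3 = a_3\sqrt{1 - (x_1/a_1)^2 - (x_2/a_2)^2}} over the planar domain
#' \deqn{D = \{(x_1, x_2):\ \beta_2 < x_1 < \beta_1,\
#'   \alpha_2 a_2 \sqrt{1-(x_1/a_1)^2} < x_2 < \alpha_1 a_2 \sqrt{1-(x_1/a_1)^2}\}.}
#' The lateral bounds \eqn{\alpha_i} are dimensionless fractions of the local
#' half-width of the ellipse; the longitudinal bounds \eqn{\beta_i} are lengths
#' along the first axis. Defaults give the full upper half-surface.
#'
#' @param a1,a2,a3 Semiaxis lengths, `a1 >= a2 >= a3 > 0` (same length units
#'   as any volume the patch will be textured from, typically mm).
#' @param alpha1,alpha2 Dimensionless lateral bounds, `|alpha_i| <= 1`,
#'   `alpha2 < alpha1`.
#' @param beta1,beta2 Longitudinal bounds, `|beta_i| <= a1`, `beta2 < beta1`.
#' @return An object of class `ellipsoid_patch`: a list with the seven
#'   parameters plus the derived shape parameters `delta1`, `delta2` and the
#'   shape flags `is_sphere`, `is_revolution`.
#' @examples
#' ellipsoid_patch(2, 1, 1)                       # full upper half-spheroid
#' ellipsoid_patch(1, 1, 1, alpha2 = 0, beta2 = 0) # unit-sphere octant
#' @export
ellipsoid_patch <- function(a1, a2, a3,
                            alpha1 = 1, alpha2 = -1,
                            beta1 = a1, beta2 = -a1) {
  stop_if <- function(bad, msg) if (bad) stop("invalid patch: ", msg, call. = FALSE)
  for (v in list(a1, a2, a3, alpha1, alpha2, beta1, beta2))
    stop_if(!is.numeric(v) || length(v) != 1L || !is.finite(v),
            "all parameters must be finite numeric scalars")
  stop_if(a3 <= 0, "semiaxes must satisfy a1 >= a2 >= a3 > 0")
  stop_if(a1 < a2 || a2 < a3, "semiaxes must satisfy a1 >= a2 >= a3 > 0")
  stop_if(abs(alpha1) > 1 || abs(alpha2) > 1, "|alpha_i| <= 1 is required")
  stop_if(abs(beta1) > a1 || abs(beta2) > a1, "|beta_i| <= a1 is required")
  stop_if(alpha2 >= alpha1, "alpha2 < alpha1 is required (nondegenerate domain)")
  stop_if(beta2 >= beta1, "beta2 < beta1 is required (nondegenerate domain)")

  spec <- list(a1 = a1, a2 = a2, a3 = a3,
               alpha1 = alpha1, alpha2 = alpha2,
               beta1 = beta1, beta2 = beta2)
  # shape classification: relative semiaxis difference below 1e-12
  spec$is_sphere     <- (a1 - a3) <= 1e-12 * a1
  spec$is_revolution <- (a2 - a3) <= 1e-12 * a1 && !spec$is_sphere
  d <- shape_deltas_values(a1, a2, a3)
  spec$delta1 <- d[1]; spec$delta2 <- d[2]
  structure(spec, class = "ellipsoid_patch")
}

shape_deltas_values <- function(a1, a2, a3) c(1 - (a3 / a1)^2, 1 - (a3 / a2)^2)

#' @export
print.ellipsoid_patch <- function(x, ...) {
  kind <- if (x$is_sphere) "sphere" else if (x$is_revolution) "ellipsoid of revolution" else "general ellipsoid"
  cat(sprintf("<ellipsoid_patch> %s, semiaxes (%g, %g, %g)\n", kind, x$a1, x$a2, x$a3))
  cat(sprintf("  alpha in (%g, %g), beta in (%g, %g)\n", x$alpha2, x$alpha1, x$beta2, x$beta1))
  cat(sprintf("  delta1 = %g, delta2 = %g\n", x$delta1, x$delta2))
  invisible(x)
}

#' Shape parameters of a patch
#'
#' Returns the dimensionless shape parameters
#' \eqn{\delta_1 = 1-(a_3/a_1)^2}, \eqn{\delta_2 = 1-(a_3/a_2)^2}
#' (which satisfy \eqn{1 > \delta_1 \ge \delta_2 \ge 0}) and, when
#' `normalize = TRUE`, the normalization constant
#' \eqn{\kappa = 1/\lambda(s(D))}, the reciprocal patch area.
#'
#' @param spec An [ellipsoid_patch()].
#' @param normalize Compute `kappa` (requires a quadrature of the patch area)?
#' @return A one-row tibble with columns `delta1`, `delta2`, `kappa` (`NA`
#'   unless `normalize = TRUE`).
#' @export
shape_deltas <- function(spec, normalize = FALSE) {
  stopifnot(inherits(spec, "ellipsoid_patch"))
  tibble::tibble(delta1 = spec$delta1, delta2 = spec$delta2,
                 kappa = if (normalize) 1 / patch_area(spec) else NA_real_)
}

# tolerance for accepting points within rounding of the closed domain
.domain_tol <- 1e-12

# is (x1, x2) in the closure of D (with clamping tolerance)?
in_domain_x <- function(spec, x1, x2, tol = .domain_tol) {
  q <- (x1 / spec$a1)^2 + (x2 / spec$a2)^2
  half <- spec$a2 * sqrt(pmax(0, 1 - (x1 / spec$a1)^2))
  q <= 1 + tol &
    x1 >= spec$beta2 - tol * spec$a1 & x1 <= spec$beta1 + tol * spec$a1 &
    x2 >= spec$alpha2 * half - tol * spec$a2 & x2 <= spec$alpha1 * half + tol * spec$a2
}

in_domain_y <- function(spec, y1, y2, tol = .domain_tol) {
  y1 >= spec$beta2 / spec$a1 - tol & y1 <= spec$beta1 / spec$a1 + tol &
    y2 >= spec$alpha2 - tol & y2 <= spec$alpha1 + tol
}

#' Evaluate the surface graph
#'
#' Lifts planar points of the domain to the upper half-ellipsoid:
#' `(x1, x2)` maps to `(x1, x2, a3 * sqrt(1 - (x1/a1)^2 - (x2/a2)^2))`.
#'
#' @param spec An [ellipsoid_patch()].
#' @param x1,x2 Numeric vectors of equal length, in the closure of the domain.
#' @return A tibble with columns `px`, `py`, `pz`.
#' @export
surface_point <- function(spec, x1, x2) {
  stopifnot(inherits(spec, "ellipsoid_patch"), length(x1) == length(x2))
  ok <- in_domain_x(spec, x1, x2)
  if (!all(ok))
    stop(sprintf("%d point(s) outside the patch domain D", sum(!ok)), call. = FALSE)
  rad <- 1 - (x1 / spec$a1)^2 - (x2 / spec$a2)^2
  tibble::tibble(px = x1, py = x2, pz = spec$a3 * sqrt(pmax(0, rad)))
}

#' Change of variables between D and the rectangle D_g
#'
#' `map_g_inverse()` maps rectangle coordinates
#' \eqn{(y_1, y_2) \in D_g = (\beta_2/a_1, \beta_1/a_1) \times (\alpha_2, \alpha_1)}
#' to the planar domain via \eqn{x_1 = a_1 y_1}, \eqn{x_2 = a_2 y_2 \sqrt{1-y_1^2}};
#' `map_g()` is its inverse. Together they put the surface-uniform density into
#' a form whose marginals are tractable.
#'
#' @param spec An [ellipsoid_patch()].
#' @param y1,y2,x1,x2 Coordinate vectors of equal length.
#' @return A tibble with columns `x1`, `x2` (or `y1`, `y2`).
#' @export
map_g_inverse <- function(spec, y1, y2) {
  stopifnot(inherits(spec, "ellipsoid_patch"), length(y1) == length(y2))
  ok <- in_domain_y(spec, y1, y2)
  if (!all(ok))
    stop(sprintf("%d point(s) outside the rectangle D_g", sum(!ok)), call. = FALSE)
  tibble::tibble(x1 = spec$a1 * y1,
                 x2 = spec$a2 * y2 * sqrt(pmax(0, 1 - y1^2)))
}

#' @rdname map_g_inverse
#' @export
map_g <- function(spec, x1, x2) {
  stopifnot(inherits(spec, "ellipsoid_patch"), length(x1) == length(x2))
  ok <- in_domain_x(spec, x1, x2)
  if (!all(ok))
    stop(sprintf("%d point(s) outside the patch domain D", sum(!ok)), call. = FALSE)
  y1 <- x1 / spec$a1
  half <- spec$a2 * sqrt(pmax(.domain_tol^2, 1 - y1^2))
  tibble::tibble(y1 = y1, y2 = pmin(1, pmax(-1, x2 / half)))
}

#' Surface-uniform density on the planar domain
#'
#' The density of the planar vector `X` whose lift `s(X)` is uniformly
#' distributed on the patch:
#' \deqn{f(x_1,x_2) = \kappa\sqrt{\frac{1-\delta_1 (x_1/a_1)^2 - \delta_2 (x_2/a_2)^2}
#'   {1-(x_1/a_1)^2-(x_2/a_2)^2}}.}
#' The density has an integrable singularity where the denominator radicand
#' vanishes (the equator of the ellipsoid); evaluation there is an error.
#'
#' @param spec An [ellipsoid_patch()].
#' @param x1,x2 Points in the domain (vectors of equal length).
#' @param normalized If `TRUE`, include the constant \eqn{\kappa}
#'   (computed by [patch_area()]); otherwise \eqn{\kappa} is replaced by 1.
#' @return Numeric vector of density values.
#' @export
density_f <- function(spec, x1, x2, normalized = FALSE) {
  stopifnot(inherits(spec, "ellipsoid_patch"), length(x1) == length(x2))
  ok <- in_domain_x(spec, x1, x2)
  if (!all(ok))
    stop(sprintf("%d point(s) outside the patch domain D", sum(!ok)), call. = FALSE)
  u1 <- (x1 / spec$a1)^2; u2 <- (x2 / spec$a2)^2
  den <- 1 - u1 - u2
  if (any(den <= 0))
    stop("density_f is singular on the equator (1 - (x1/a1)^2 - (x2/a2)^2 <= 0)",
         call. = FALSE)
  k <- if (normalized) 1 / patch_area(spec) else 1
  k * sqrt((1 - spec$delta1 * u1 - spec$delta2 * u2) / den)
}

# m(y1) of the transformed density; shared by density_fg and quadrature
m_of_y1 <- function(spec, y1) spec$delta2 * (1 - y1^2) / (1 - spec$delta1 * y1^2)

#' Surface-uniform density in rectangle coordinates
#'
#' The density of `Y = g(X)` on the rectangle `D_g`:
#' \deqn{f_g(y_1,y_2) = \kappa\, a_1 a_2
#'   \sqrt{\frac{(1-\delta_1 y_1^2)(1 - m(y_1)\,y_2^2)}{1-y_2^2}},\qquad
#'   m(y_1) = \frac{\delta_2 (1-y_1^2)}{1-\delta_1 y_1^2}.}
#' For a sphere this reduces to \eqn{\kappa a_1^2/\sqrt{1-y_2^2}}; for an
#' ellipsoid of revolution the \eqn{m} term drops and the two coordinates are
#' independent.
#'
#' @inheritParams density_f
#' @param y1,y2 Points in `D_g` (vectors of equal length); `|y2| < 1`.
#' @return Numeric vector of density values.
#' @export
density_fg <- function(spec, y1, y2, normalized = FALSE) {
  stopifnot(inherits(spec, "ellipsoid_patch"), length(y1) == length(y2))
  ok <- in_domain_y(spec, y1, y2)
  if (!all(ok))
    stop(sprintf("%d point(s) outside the rectangle D_g", sum(!ok)), call. = FALSE)
  if (any(abs(y2) >= 1))
    stop("density_fg is singular at |y2| = 1", call. = FALSE)
  k <- if (normalized) 1 / patch_area(spec) else 1
  k * spec$a1 * spec$a2 *
    sqrt((1 - spec$delta1 * y1^2) * (1 - m_of_y1(spec, y1) * y2^2) / (1 - y2^2))
}

# Unnormalized log density on D_g (used by the Hastings samplers); -Inf outside.
log_fg_unnormalized <- function(spec) {
  d1 <- spec$delta1
  lo1 <- spec$beta2 / spec$a1; hi1 <- spec$beta1 / spec$a1
  lo2 <- spec$alpha2; hi2 <- spec$alpha1
  function(y) {
    y1 <- y[1]; y2 <- y[2]
    if (y1 <= lo1 || y1 >= hi1 || y2 <= lo2 || y2 >= hi2 || abs(y2) >= 1) return(-Inf)
    0.5 * (log1p(-d1 * y1^2) + log1p(-m_of_y1(spec, y1) * y2^2) - log1p(-y2^2))
  }
}

# Surface area of the image of the sub-rectangle [y1a,y1b] x [y2a,y2b] of D_g.
# Integrates the transformed area element; the 1/sqrt(1-y2^2) endpoint
# singularity is removed by the substitution y2 = sin(theta), leaving the
# smooth integrand a1 a2 sqrt(1-delta1 y1^2) sqrt(1 - m(y1) sin^2 theta).
area_region_y <- function(spec, y1a, y1b, y2a, y2b, rel.tol = 1e-10) {
  th_a <- asin(max(-1, min(1, y2a))); th_b <- asin(max(-1, min(1, y2b)))
  inner <- function(y1) {
    m <- m_of_y1(spec, y1)
    f1 <- sqrt(1 - spec$delta1 * y1^2)
    vapply(seq_along(y1), function(i) {
      if (m[i] < 1e-14) f1[i] * (th_b - th_a)  # sphere / revolution shortcut
      else f1[i] * stats::integrate(function(th) sqrt(1 - m[i] * sin(th)^2),
                                    th_a, th_b, rel.tol = rel.tol,
                                    abs.tol = 0)$value
    }, numeric(1))
  }
  out <- stats::integrate(inner, y1a, y1b, rel.tol = rel.tol, abs.tol = 0)
  if (out$message != "OK")
    stop("patch area quadrature failed: ", out$message, call. = FALSE)
  spec$a1 * spec$a2 * out$value
}

#' Surface area of a patch
#'
#' Computes \eqn{\lambda(s(D))} by adaptive quadrature of the surface area
#' element in rectangle coordinates, where the boundary singularity of the
#' integrand reduces to the integrable factor \eqn{1/\sqrt{1-y_2^2}} and is
#' removed exactly by the substitution \eqn{y_2 = \sin\theta}.
#'
#' @param spec An [ellipsoid_patch()].
#' @param rel.tol Relative quadrature accuracy target.
#' @return The patch area (squared length units).
#' @examples
#' patch_area(ellipsoid_patch(1, 1, 1))  # upper half of unit sphere: 2*pi
#' @export
patch_area <- function(spec, rel.tol = 1e-10) {
  stopifnot(inherits(spec, "ellipsoid_patch"))
  area_region_y(spec, spec$beta2 / spec$a1, spec$beta1 / spec$a1,
                spec$alpha2, spec$alpha1, rel.tol = rel.tol)
}

#' Read and write patch configurations
#'
#' Patch specifications are serialized as a flat `key = value` text block with
#' 17 significant digits, so a written and re-read patch is bit-identical.
#'
#' @param spec An [ellipsoid_patch()].
#' @param path File path.
#' @return `read_patch_config()` returns an [ellipsoid_patch()];
#'   `write_patch_config()` returns `path` invisibly.
#' @export
write_patch_config <- function(spec, path) {
  stopifnot(inherits(spec, "ellipsoid_patch"))
  keys <- c("a1", "a2", "a3", "alpha1", "alpha2", "beta1", "beta2")
  writeLines(sprintf("%s = %.17g", keys, unlist(spec[keys])), path)
  invisible(path)
}

#' @rdname write_patch_config
#' @export
read_patch_config <- function(path) {
  kv <- parse_flat_config(path)
  keys <- c("a1", "a2", "a3", "alpha1", "alpha2", "beta1", "beta2")
  missing <- setdiff(keys, names(kv))
  if (length(missing))
    stop("patch config missing keys: ", paste(missing, collapse = ", "), call. = FALSE)
  do.call(ellipsoid_patch, as.list(as.numeric(kv[keys])))
}

# shared flat "key = value" parser (also used for phantom specs and CLI configs)
parse_flat_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  stats::setNames(vapply(parts, function(p) trimws(paste(p[-1], collapse = "=")), ""),
                  vapply(parts, function(p) trimws(p[1]), ""))
}
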