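# The antiderivative phi of sqrt(1 - delta1 t^2) and its tabulated inverse.
# phi drives the inverse-transform sampler of the y1 marginal on an ellipsoid
# of revolution: Z = sqrt(delta1) * Y1 follows the semicircular law with
# density proportional to sqrt(1 - z^2), whose CDF is phi(.; 1) rescaled.

#' Antiderivative of the semicircular density kernel
#'
#' \deqn{\phi(t;\delta_1) = \int_0^t \sqrt{1-\delta_1 s^2}\, ds
#'  = \frac{1}{2\sqrt{\delta_1}}\left(\sqrt{\delta_1}\,t\sqrt{1-\delta_1 t^2}
#'    + \arcsin(\sqrt{\delta_1}\, t)\right).}
#' Strictly increasing on \eqn{|t| \le 1/\sqrt{\delta_1}}, odd, with
#' \eqn{\phi(1;1) = \pi/4}.
#'
#' @param t Numeric vector, `|t| * sqrt(delta1) <= 1`.
#' @param delta1 Shape parameter in `(0, 1]`. `delta1 = 0` is an error: the
#'   integrand is constant and the sphere branch applies.
#' @return Numeric vector of the same length as `t`.
#' @export
phi <- function(t, delta1 = 1) {
  stopifnot(is.numeric(t), length(delta1) == 1L)
  if (delta1 <= 0 || delta1 > 1)
    stop("delta1 must be in (0, 1]; for delta1 = 0 use the sphere branch",
         call. = FALSE)
  sd1 <- sqrt(delta1)
  z <- sd1 * t
  if (any(abs(z) > 1 + 1e-12))
    stop("|t| * sqrt(delta1) > 1: outside the support of sqrt(1 - delta1 t^2)",
         call. = FALSE)
  z <- pmin(1, pmax(-1, z))
  (z * sqrt(1 - z^2) + asin(z)) / (2 * sd1)
}

#' Tabulated inverse of the semicircular CDF kernel
#'
#' Builds a monotone piecewise-cubic Hermite interpolant (Fritsch-Carlson,
#' `stats::splinefun(method = "monoH.FC")`) of \eqn{\phi^{-1}(\cdot;1)} from
#' the swapped table \eqn{\{\phi(s_k;1), s_k\}} on Chebyshev-spaced knots
#' \eqn{s_k \in [-1,1]}. Chebyshev spacing clusters knots near \eqn{\pm 1}
#' where \eqn{\phi'} vanishes and the inverse steepens. The interpolant is
#' shape preserving: it cannot overshoot the monotone data.
#'
#' @param n_knots Number of knots (at least 4; default 200 keeps the residual
#'   `|phi(interp(u); 1) - u|` below 1e-6 over the whole range).
#' @return An object of class `semicircular_transform`: list with the
#'   interpolating function `fun`, the knot abscissae `knots` (in u), knot
#'   ordinates `values` (in t), and `u_range = c(phi(-1;1), phi(1;1))`.
#' @export
build_phi_inverse <- function(n_knots = 200) {
  stopifnot(is.numeric(n_knots), length(n_knots) == 1L, n_knots >= 4)
  n_knots <- as.integer(n_knots)
  s <- -cos(pi * (0:(n_knots - 1)) / (n_knots - 1))  # Chebyshev points on [-1, 1]
  u <- phi(s, 1)
  structure(list(fun = stats::splinefun(u, s, method = "monoH.FC"),
                 knots = u, values = s, n_knots = n_knots,
                 u_range = c(-pi / 4, pi / 4)),
            class = "semicircular_transform")
}

#' @export
print.semicircular_transform <- function(x, ...) {
  cat(sprintf("<semicircular_transform> %d Chebyshev knots on [-pi/4, pi/4]\n",
              x$n_knots))
  invisible(x)
}

#' Residual of a semicircular transform
#'
#' Maximum of `|phi(interp(u); 1) - u|` over a dense probe grid, the accuracy
#' measure for the tabulated inverse.
#'
#' @param transform A [build_phi_inverse()] object.
#' @param n_probe Number of probe points spanning the full u-range.
#' @return The maximum absolute residual.
#' @export
phi_inverse_residual <- function(transform, n_probe = 1e5) {
  stopifnot(inherits(transform, "semicircular_transform"))
  u <- seq(transform$u_range[1], transform$u_range[2], length.out = n_probe)
  t <- pmin(1, pmax(-1, transform$fun(u)))
  max(abs(phi(t, 1) - u))
}
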