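# broom-style accessors for fitted objects and diagnostics.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted quadric
#'
#' One row per parameter (center coordinates and semiaxes), in world units.
#'
#' @param x A `fitted_quadric` from [fit_sphere_lsq()] or
#'   [fit_ellipsoid_revolution_lsq()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.fitted_quadric <- function(x, ...) {
  tibble::tibble(term = c("center_x", "center_y", "center_z",
                          "a1", "a2", "a3"),
                 estimate = c(x$center, x$semiaxes))
}

#' Glance at a fitted quadric
#'
#' @inheritParams tidy.fitted_quadric
#' @return A one-row tibble with `kind`, `n`, `rss`, `radius` (sphere fits
#'   only, else `NA`).
#' @export
glance.fitted_quadric <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = x$n, rss = x$rss,
                 radius = if (x$kind == "sphere") x$semiaxes[1] else NA_real_)
}
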