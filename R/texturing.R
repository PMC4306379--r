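# Voxel volumes, trilinear gray-value interpolation, and least-squares
# fitting of spheres / ellipsoids of revolution to landmark point clouds.
#
# Coordinate convention (fixed throughout the package): voxel indices are
# 0-based; the world position of voxel (i,j,k) is origin + (i,j,k) * spacing,
# i.e. `origin` is the world position of the CENTER of voxel (0,0,0). The
# interpolable box ends at the outermost voxel centers; there is no
# extrapolation beyond them.

#' Construct a voxel volume
#'
#' @param values 3-D numeric array of gray values.
#' @param spacing Per-axis voxel size (length 3, mm, > 0).
#' @param origin World position of the center of voxel `(0,0,0)` (length 3, mm).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            length(spacing) == 3, all(spacing > 0),
            length(origin) == 3, all(is.finite(origin)))
  if (any(dim(values) < 2))
    stop("each axis needs at least 2 voxels (trilinear interpolation needs a cell)",
         call. = FALSE)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), dims = dim(values)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, spacing (%g, %g, %g) mm\n",
              paste(x$dims, collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, gray range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# vectorized trilinear core; returns list(gray, inside)
trilinear_core <- function(volume, px, py, pz) {
  d <- volume$dims
  cx <- (px - volume$origin[1]) / volume$spacing[1]
  cy <- (py - volume$origin[2]) / volume$spacing[2]
  cz <- (pz - volume$origin[3]) / volume$spacing[3]
  tol <- 1e-9
  inside <- cx >= -tol & cx <= d[1] - 1 + tol &
            cy >= -tol & cy <= d[2] - 1 + tol &
            cz >= -tol & cz <= d[3] - 1 + tol
  gray <- rep(NA_real_, length(px))
  if (any(inside)) {
    cx <- pmin(pmax(cx[inside], 0), d[1] - 1)
    cy <- pmin(pmax(cy[inside], 0), d[2] - 1)
    cz <- pmin(pmax(cz[inside], 0), d[3] - 1)
    i0 <- pmin(floor(cx), d[1] - 2); fx <- cx - i0
    j0 <- pmin(floor(cy), d[2] - 2); fy <- cy - j0
    k0 <- pmin(floor(cz), d[3] - 2); fz <- cz - k0
    v <- volume$values
    lin <- function(i, j, k) v[cbind(i + 1, j + 1, k + 1)]  # 0-based -> R index
    g <- lin(i0,     j0,     k0    ) * (1 - fx) * (1 - fy) * (1 - fz) +
         lin(i0 + 1, j0,     k0    ) * fx       * (1 - fy) * (1 - fz) +
         lin(i0,     j0 + 1, k0    ) * (1 - fx) * fy       * (1 - fz) +
         lin(i0 + 1, j0 + 1, k0    ) * fx       * fy       * (1 - fz) +
         lin(i0,     j0,     k0 + 1) * (1 - fx) * (1 - fy) * fz +
         lin(i0 + 1, j0,     k0 + 1) * fx       * (1 - fy) * fz +
         lin(i0,     j0 + 1, k0 + 1) * (1 - fx) * fy       * fz +
         lin(i0 + 1, j0 + 1, k0 + 1) * fx       * fy       * fz
    gray[inside] <- g
  }
  list(gray = gray, inside = inside)
}

#' Trilinear interpolation at a single world point
#'
#' Blends the 8 corner voxels of the cell containing `p` with the standard
#' trilinear weights. The result is exact at voxel centers and for gray
#' fields affine in the world coordinates, and always lies between the min
#' and max of the 8 corners.
#'
#' @param volume A [voxel_volume()].
#' @param p World coordinates (length-3 numeric).
#' @return The interpolated gray value (scalar). Points outside the
#'   interpolable box raise an error; use [texture_points()] for per-point
#'   flagging.
#' @export
trilinear_sample <- function(volume, p) {
  stopifnot(inherits(volume, "voxel_volume"), length(p) == 3)
  res <- trilinear_core(volume, p[1], p[2], p[3])
  if (!res$inside)
    stop("point outside the interpolable box (outermost voxel centers)",
         call. = FALSE)
  res$gray
}

#' Texture a point cloud from a voxel volume
#'
#' Applies trilinear interpolation to every point; points outside the
#' interpolable box are flagged (`inside = FALSE`, `gray = NA`) rather than
#' dropped, so the output always has one row per input point.
#'
#' @param points A data frame with world-coordinate columns `px`, `py`, `pz`
#'   (or `x`, `y`, `z`); a `sample_batch` works directly.
#' @param volume A [voxel_volume()].
#' @return A tibble of class `textured_cloud` with columns `px`, `py`, `pz`,
#'   `gray`, `inside`.
#' @export
texture_points <- function(points, volume) {
  stopifnot(is.data.frame(points), inherits(volume, "voxel_volume"))
  nm <- if (all(c("px", "py", "pz") %in% names(points))) c("px", "py", "pz")
        else if (all(c("x", "y", "z") %in% names(points))) c("x", "y", "z")
        else stop("points needs columns px/py/pz or x/y/z", call. = FALSE)
  if (nrow(points) == 0)
    return(structure(tibble::tibble(px = numeric(), py = numeric(),
                                    pz = numeric(), gray = numeric(),
                                    inside = logical()),
                     class = c("textured_cloud", class(tibble::tibble()))))
  res <- trilinear_core(volume, points[[nm[1]]], points[[nm[2]]], points[[nm[3]]])
  out <- tibble::tibble(px = points[[nm[1]]], py = points[[nm[2]]],
                        pz = points[[nm[3]]], gray = res$gray,
                        inside = res$inside)
  structure(out, class = c("textured_cloud", class(out)))
}

# -- least-squares quadric fitting ------------------------------------------

new_fitted_quadric <- function(center, semiaxes, kind, rss, n, axis = NULL) {
  structure(list(center = center, semiaxes = semiaxes, kind = kind,
                 rss = rss, n = n, axis = axis),
            class = "fitted_quadric")
}

#' @export
print.fitted_quadric <- function(x, ...) {
  cat(sprintf("<fitted_quadric> %s: center (%.4g, %.4g, %.4g), semiaxes (%.4g, %.4g, %.4g)\n",
              x$kind, x$center[1], x$center[2], x$center[3],
              x$semiaxes[1], x$semiaxes[2], x$semiaxes[3]))
  cat(sprintf("  n = %d, algebraic RSS = %.4g\n", x$n, x$rss))
  invisible(x)
}

points_matrix <- function(points) {
  nm <- if (all(c("px", "py", "pz") %in% names(points))) c("px", "py", "pz")
        else if (all(c("x", "y", "z") %in% names(points))) c("x", "y", "z")
        else stop("points needs columns px/py/pz or x/y/z", call. = FALSE)
  as.matrix(points[nm])
}

#' Least-squares sphere fit
#'
#' Algebraic fit: the sphere equation
#' \eqn{x^2+y^2+z^2 = 2 c\cdot x + (r^2 - \|c\|^2)} is linear in the center
#' and the radius term, so the fit is a single linear solve. Exact data are
#' recovered exactly.
#'
#' @param points A data frame with columns `px`, `py`, `pz` (or `x`, `y`,
#'   `z`); at least 4 non-coplanar points.
#' @return A `fitted_quadric` with `kind = "sphere"` (equal semiaxes) and the
#'   algebraic residual sum of squares.
#' @export
fit_sphere_lsq <- function(points) {
  P <- points_matrix(points)
  if (nrow(P) < 4) stop("sphere fit needs at least 4 points", call. = FALSE)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4)
    stop("degenerate point configuration (coplanar or coincident points)",
         call. = FALSE)
  theta <- unname(qr.coef(qr_A, b))
  center <- theta[1:3]
  r2 <- theta[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate fit: nonpositive squared radius", call. = FALSE)
  r <- sqrt(r2)
  rss <- sum((b - A %*% theta)^2)
  new_fitted_quadric(unname(center), rep(r, 3), "sphere", rss, nrow(P))
}

# orthonormal frame with third column = axis
axis_frame <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  h <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- h - sum(h * a) * a; u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  cbind(u, v, a)
}

#' Least-squares fit of an ellipsoid of revolution
#'
#' Fits an ellipsoid of revolution with the given (known) symmetry axis:
#' writing `t` for the coordinate along the axis and `(u, v)` for transverse
#' coordinates, the surface \eqn{(t-c_t)^2/a_1^2 + ((u-c_u)^2+(v-c_v)^2)/a_2^2 = 1}
#' linearizes to \eqn{t^2 + b(u^2+v^2) + c t + d u + e v + f = 0}, solved by
#' ordinary least squares. The symmetry axis is not estimated; it must be
#' supplied (for the humerus, the shaft direction) and defaults to the volume
#' z-axis.
#'
#' @param points A data frame with columns `px`, `py`, `pz` (or `x`, `y`, `z`);
#'   at least 6 points in general position.
#' @param axis Symmetry-axis direction (length-3, need not be normalized).
#' @return A `fitted_quadric` with `kind = "revolution"`, semiaxes
#'   `(a_axis, a_trans, a_trans)` in world units and the axis recorded.
#' @export
fit_ellipsoid_revolution_lsq <- function(points, axis = c(0, 0, 1)) {
  P <- points_matrix(points)
  if (nrow(P) < 6) stop("revolution fit needs at least 6 points", call. = FALSE)
  Fr <- axis_frame(axis)
  Q <- P %*% Fr                       # columns: u, v, t
  u <- Q[, 1]; v <- Q[, 2]; t <- Q[, 3]
  A <- cbind(u^2 + v^2, t, u, v, 1)
  b <- -t^2
  qr_A <- qr(A)
  if (qr_A$rank < 5)
    stop("degenerate point configuration for revolution fit", call. = FALSE)
  th <- unname(qr.coef(qr_A, b))
  if (th[1] <= 0)
    stop("degenerate fit: points do not determine an ellipsoid of revolution",
         call. = FALSE)
  bb <- th[1]
  ct <- -th[2] / 2
  cu <- -th[3] / (2 * bb); cv <- -th[4] / (2 * bb)
  a1sq <- ct^2 + bb * (cu^2 + cv^2) - th[5]
  if (a1sq <= 0 || a1sq / bb <= 0)
    stop("degenerate fit: nonpositive squared semiaxis", call. = FALSE)
  a_axis <- sqrt(a1sq)
  a_trans <- sqrt(a1sq / bb)
  center <- Fr %*% c(cu, cv, ct)
  rss <- sum((b - A %*% th)^2)
  new_fitted_quadric(as.numeric(center), c(a_axis, a_trans, a_trans),
                     "revolution", rss, nrow(P), axis = Fr[, 3])
}

#' Patch specification from a fitted quadric
#'
#' Converts a [fit_sphere_lsq()] / [fit_ellipsoid_revolution_lsq()] result
#' into an [ellipsoid_patch()] (semiaxes sorted decreasingly), together with
#' the world-frame placement needed to map patch coordinates back to the
#' volume: points sampled on the patch live in the quadric's principal frame
#' centered at the fitted center.
#'
#' @param fit A `fitted_quadric`.
#' @param alpha1,alpha2,beta1,beta2 Patch bounds, as in [ellipsoid_patch()]
#'   (defaults: full upper half-surface, beta as fractions of `a1`).
#' @return A list with `spec` (the patch), `center`, and `frame` (3x3 matrix
#'   whose columns map patch axes to world axes).
#' @export
patch_from_fit <- function(fit, alpha1 = 1, alpha2 = -1, beta1 = NULL,
                           beta2 = NULL) {
  stopifnot(inherits(fit, "fitted_quadric"))
  if (fit$kind == "sphere") {
    a <- fit$semiaxes
    frame <- diag(3)
  } else {
    ord <- order(fit$semiaxes, decreasing = TRUE)
    a <- fit$semiaxes[ord]
    Fr <- axis_frame(fit$axis)        # columns u, v, axis
    # patch x1-axis must carry the largest semiaxis
    frame <- if (ord[1] == 1) Fr[, c(3, 1, 2)] else Fr[, c(1, 2, 3)]
  }
  spec <- ellipsoid_patch(a[1], a[2], a[3],
                          alpha1 = alpha1, alpha2 = alpha2,
                          beta1 = if (is.null(beta1)) a[1] else beta1,
                          beta2 = if (is.null(beta2)) -a[1] else beta2)
  list(spec = spec, center = fit$center, frame = frame)
}

#' Map patch-frame surface points to world coordinates
#'
#' @param batch A `sample_batch` (or data frame with `px`, `py`, `pz`).
#' @param placement A list with `center` and `frame` as from
#'   [patch_from_fit()].
#' @return A tibble with world-coordinate columns `px`, `py`, `pz`.
#' @export
to_world <- function(batch, placement) {
  P <- points_matrix(batch)
  W <- P %*% t(placement$frame)
  tibble::tibble(px = W[, 1] + placement$center[1],
                 py = W[, 2] + placement$center[2],
                 pz = W[, 3] + placement$center[3])
}
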