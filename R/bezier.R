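# Rational triangular Bezier patches: control nets stored as tibbles
# (i1, i2, i3, x, y, z, w) in lexicographic (i1, i2) order, evaluated either
# by the weighted de Casteljau recursion or by the rational Bernstein form.

multi_indices <- function(n) {
  g <- expand.grid(i2 = 0:n, i1 = 0:n)
  g <- g[g$i1 + g$i2 <= n, c("i1", "i2")]
  g <- g[order(g$i1, g$i2), ]
  tibble::tibble(i1 = g$i1, i2 = g$i2, i3 = n - g$i1 - g$i2)
}

#' Construct a rational triangular Bezier patch
#'
#' @param control_points A data frame with columns `i1`, `i2`, `i3` (the
#'   multi-index, summing to the degree for every row), `x`, `y`, `z` (control
#'   point coordinates) and `w` (strictly positive weight). Exactly
#'   `(n+1)(n+2)/2` rows for degree `n`.
#' @return An object of classes `bezier_patch`/`tbl_df`, rows sorted
#'   lexicographically by `(i1, i2)`, with the degree as attribute `degree`.
#' @export
bezier_patch <- function(control_points) {
  cp <- tibble::as_tibble(control_points)
  need <- c("i1", "i2", "i3", "x", "y", "z", "w")
  if (!all(need %in% names(cp)))
    stop("control_points needs columns ", paste(need, collapse = ", "), call. = FALSE)
  n <- cp$i1[1] + cp$i2[1] + cp$i3[1]
  if (any(cp$i1 + cp$i2 + cp$i3 != n) || any(cp$i1 < 0 | cp$i2 < 0 | cp$i3 < 0))
    stop("every multi-index must have nonnegative parts summing to the degree",
         call. = FALSE)
  if (nrow(cp) != (n + 1) * (n + 2) / 2 ||
      anyDuplicated(cp[c("i1", "i2", "i3")]))
    stop(sprintf("degree %d patch needs exactly %d distinct control points",
                 n, (n + 1) * (n + 2) / 2), call. = FALSE)
  if (any(cp$w <= 0))
    stop("all weights must be strictly positive", call. = FALSE)
  cp <- cp[order(cp$i1, cp$i2), ]
  structure(cp, degree = n, class = c("bezier_patch", class(cp)))
}

#' @export
print.bezier_patch <- function(x, ...) {
  cat(sprintf("<bezier_patch> rational triangular patch, degree %d\n",
              attr(x, "degree")))
  NextMethod()
}

check_barycentric <- function(u) {
  u <- as.matrix(u)
  if (ncol(u) != 3) stop("barycentric coordinates need 3 columns", call. = FALSE)
  if (any(abs(rowSums(u) - 1) > 1e-12))
    stop("barycentric coordinates must sum to 1", call. = FALSE)
  if (any(u < -1e-12))
    stop("domain barycentric coordinates must be nonnegative", call. = FALSE)
  pmax(u, 0)
}

#' Evaluate a patch by the rational de Casteljau recursion
#'
#' Runs the weighted convex-combination recursion: at each level the weights
#' are blended as \eqn{w_i^{(r)} = u w_{i+e_1} + v w_{i+e_2} + w w_{i+e_3}}
#' and the points as the weight-carried average
#' \eqn{b_i^{(r)} = (u w_{i+e_1} b_{i+e_1} + v w_{i+e_2} b_{i+e_2} +
#' w w_{i+e_3} b_{i+e_3}) / w_i^{(r)}}, down to the single point
#' \eqn{b_0^{(n)}(u)}.
#'
#' @param patch A [bezier_patch()].
#' @param u Barycentric coordinates: length-3 vector or 3-column matrix /
#'   data frame (columns `u`, `v`, `w`), each row summing to 1.
#' @return A tibble with columns `px`, `py`, `pz`, one row per parameter.
#' @export
de_casteljau <- function(patch, u) {
  stopifnot(inherits(patch, "bezier_patch"))
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  u <- check_barycentric(u)
  n <- attr(patch, "degree")
  # per-level child index triples, built once: level d holds, for each
  # multi-index of degree d-1, the rows of its three degree-d children
  levels <- lapply(0:n, multi_indices)
  children <- lapply(1:n, function(d) {
    mi <- levels[[d]]
    key <- stats::setNames(seq_len(nrow(levels[[d + 1]])),
                           paste(levels[[d + 1]]$i1, levels[[d + 1]]$i2,
                                 sep = ","))
    list(k1 = unname(key[paste(mi$i1 + 1, mi$i2, sep = ",")]),
         k2 = unname(key[paste(mi$i1, mi$i2 + 1, sep = ",")]),
         k3 = unname(key[paste(mi$i1, mi$i2, sep = ",")]))
  })
  out <- matrix(NA_real_, nrow(u), 3)
  P0 <- as.matrix(patch[, c("x", "y", "z")])
  W0 <- patch$w
  for (row in seq_len(nrow(u))) {
    uu <- u[row, 1]; vv <- u[row, 2]; ww <- u[row, 3]
    P <- P0; W <- W0
    for (d in n:1) {
      k1 <- children[[d]]$k1; k2 <- children[[d]]$k2; k3 <- children[[d]]$k3
      Wn <- uu * W[k1] + vv * W[k2] + ww * W[k3]
      P <- (uu * W[k1] * P[k1, , drop = FALSE] +
            vv * W[k2] * P[k2, , drop = FALSE] +
            ww * W[k3] * P[k3, , drop = FALSE]) / Wn
      W <- Wn
    }
    out[row, ] <- P[1, ]
  }
  tibble::tibble(px = out[, 1], py = out[, 2], pz = out[, 3])
}

bernstein_basis <- function(n, u) {
  mi <- multi_indices(n)
  coef <- factorial(n) / (factorial(mi$i1) * factorial(mi$i2) * factorial(mi$i3))
  # N_points x N_control basis matrix
  B <- outer(u[, 1], mi$i1, `^`) * outer(u[, 2], mi$i2, `^`) *
    outer(u[, 3], mi$i3, `^`)
  sweep(B, 2, coef, `*`)
}

#' Evaluate a patch by the rational Bernstein representation
#'
#' Computes \eqn{b^n(u) = \sum_i w_i b_i B_i^n(u) / \sum_i w_i B_i^n(u)} with
#' the homogeneous Bernstein polynomials
#' \eqn{B_i^n(u) = \binom{n}{i_1 i_2 i_3} u^{i_1} v^{i_2} w^{i_3}}.
#' Mathematically identical to [de_casteljau()]; the closed form vectorizes
#' over many parameter values at once.
#'
#' @inheritParams de_casteljau
#' @return A tibble with columns `px`, `py`, `pz`.
#' @export
bernstein_eval <- function(patch, u) {
  stopifnot(inherits(patch, "bezier_patch"))
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  u <- check_barycentric(u)
  B <- bernstein_basis(attr(patch, "degree"), u)
  den <- as.numeric(B %*% patch$w)
  if (any(den <= 0))
    stop("internal error: nonpositive rational denominator", call. = FALSE)
  num <- B %*% (patch$w * as.matrix(patch[, c("x", "y", "z")]))
  tibble::tibble(px = num[, 1] / den, py = num[, 2] / den, pz = num[, 3] / den)
}

# -- exact degree-4 sphere octant -------------------------------------------
# Built by composing a rational quadratic triangular patch mapping the domain
# triangle onto the quarter disc {p,q >= 0, p^2+q^2 <= 1} with the inverse
# stereographic projection (p,q) -> (2p, 2q, 1-p^2-q^2)/(1+p^2+q^2). Both
# maps are homogeneous quadratics, so the composite is an exact degree-4
# rational patch whose image is the positive octant of the unit sphere.

poly_mul <- function(p, q) {
  out <- list()
  for (np in names(p)) for (nq in names(q)) {
    ep <- as.integer(strsplit(np, ",")[[1]]) + as.integer(strsplit(nq, ",")[[1]])
    k <- paste(ep, collapse = ",")
    out[[k]] <- (out[[k]] %||% 0) + p[[np]] * q[[nq]]
  }
  unlist(out)
}

poly_add <- function(...) {
  ps <- list(...)
  keys <- unique(unlist(lapply(ps, names)))
  stats::setNames(vapply(keys, function(k)
    sum(vapply(ps, function(p) if (k %in% names(p)) p[[k]] else 0, 0)), 0), keys)
}

octant_net <- local({
  net <- NULL
  function() {
    if (!is.null(net)) return(net)
    s2 <- sqrt(2)
    # homogeneous components of the quadratic quarter-disc patch, monomial form
    P <- c("2,0,0" = 1, "1,1,0" = s2, "1,0,1" = 1)
    Q <- c("0,2,0" = 1, "1,1,0" = s2, "0,1,1" = 1)
    R <- c("2,0,0" = 1, "0,2,0" = 1, "0,0,2" = 1,
           "1,1,0" = s2, "1,0,1" = 2, "0,1,1" = 2)
    X <- 2 * poly_mul(P, R); Y <- 2 * poly_mul(Q, R)
    Z <- poly_add(poly_mul(R, R), -poly_mul(P, P), -poly_mul(Q, Q))
    W <- poly_add(poly_mul(R, R), poly_mul(P, P), poly_mul(Q, Q))
    mi <- multi_indices(4)
    bern_coef <- function(p) vapply(seq_len(nrow(mi)), function(k) {
      key <- paste(c(mi$i1[k], mi$i2[k], mi$i3[k]), collapse = ",")
      v <- if (key %in% names(p)) p[[key]] else 0
      v * factorial(mi$i1[k]) * factorial(mi$i2[k]) * factorial(mi$i3[k]) /
        factorial(4)
    }, numeric(1))
    cw <- bern_coef(W)
    net <<- tibble::tibble(i1 = mi$i1, i2 = mi$i2, i3 = mi$i3,
                           x = bern_coef(X) / cw, y = bern_coef(Y) / cw,
                           z = bern_coef(Z) / cw, w = cw)
    net
  }
})

#' Exact degree-4 rational patch for a sphere octant
#'
#' Returns a degree-4 rational triangular Bezier patch whose image is exactly
#' the positive octant of the sphere of the given radius, with corners at
#' `(r,0,0)`, `(0,r,0)`, `(0,0,r)`. The control net comes from the exact
#' rational representation of the octant (composition of a quadratic
#' quarter-disc patch with the inverse stereographic projection); the
#' boundary curves are the standard rational quarter circles.
#'
#' @param radius Sphere radius (> 0).
#' @return A [bezier_patch()] of degree 4 (15 control points).
#' @export
sphere_octant_patch <- function(radius = 1) {
  stopifnot(radius > 0)
  net <- octant_net()
  net$x <- net$x * radius; net$y <- net$y * radius; net$z <- net$z * radius
  bezier_patch(net)
}

#' Degree-4 rational patch for an ellipsoid octant
#'
#' Anisotropic scaling of the unit-sphere octant control net by the semiaxes
#' (weights unchanged): rational patches are invariant under affine maps of
#' their control points, so the image is exactly the positive octant of the
#' ellipsoid \eqn{(x/a_1)^2+(y/a_2)^2+(z/a_3)^2 = 1}.
#'
#' @param a1,a2,a3 Semiaxis lengths (> 0).
#' @return A [bezier_patch()] of degree 4.
#' @export
ellipsoid_octant_patch <- function(a1, a2, a3) {
  stopifnot(a1 > 0, a2 > 0, a3 > 0)
  net <- octant_net()
  net$x <- net$x * a1; net$y <- net$y * a2; net$z <- net$z * a3
  bezier_patch(net)
}

#' Deterministic barycentric evaluation lattice
#'
#' The triangular lattice \eqn{\{(i/m, j/m, (m-i-j)/m)\}} with
#' \eqn{(m+1)(m+2)/2} points, in lexicographic `(i, j)` order. `m = 44`
#' gives 1035 points.
#'
#' @param m Lattice resolution (>= 1).
#' @return A tibble with columns `u`, `v`, `w`.
#' @export
barycentric_grid <- function(m) {
  stopifnot(m >= 1)
  m <- as.integer(m)
  g <- expand.grid(j = 0:m, i = 0:m)
  g <- g[g$i + g$j <= m, ]
  g <- g[order(g$i, g$j), ]
  tibble::tibble(u = g$i / m, v = g$j / m, w = (m - g$i - g$j) / m)
}

#' First n deterministic barycentric parameters
#'
#' The full lattice of the largest resolution whose triangular count fits in
#' `n`, padded with the leading points of the next finer lattice. Used by the
#' benchmark harness and the deterministic `evaluate` command, whose batch
#' sizes need not be triangular numbers.
#'
#' @param n Number of points (>= 1).
#' @return A tibble with columns `u`, `v`, `w` and exactly `n` rows.
#' @export
barycentric_points_n <- function(n) {
  stopifnot(n >= 1)
  m <- floor((sqrt(8 * n + 1) - 3) / 2)
  while ((m + 1) * (m + 2) / 2 > n) m <- m - 1
  base <- barycentric_grid(max(m, 1))
  if (nrow(base) >= n) return(base[seq_len(n), ])
  extra <- barycentric_grid(m + 1)
  dplyr::bind_rows(base, extra[seq_len(n - nrow(base)), ])
}

#' Read and write control nets as CSV
#'
#' @param patch A [bezier_patch()].
#' @param path File path.
#' @return `read_control_net()` returns a [bezier_patch()].
#' @export
write_control_net <- function(patch, path) {
  stopifnot(inherits(patch, "bezier_patch"))
  readr::write_csv(tibble::as_tibble(patch), path)
  invisible(path)
}

#' @rdname write_control_net
#' @export
read_control_net <- function(path) {
  bezier_patch(readr::read_csv(path, show_col_types = FALSE))
}
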