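# Uniformity diagnostics: chi-square test over a rectangular grid in the
# rectangle coordinates, with each cell's expected count proportional to the
# true surface area of its image (computed by quadrature). Grid lines are
# placed at marginal area quantiles so cells have (approximately) equal
# surface area and hence uniform expected counts.

# Marginal cumulative-area quantile edges along one y-coordinate. Edge
# placement only aims at near-equal cell areas; expected counts are later
# computed from exact per-cell quadratures, so grid-level approximation here
# does not bias the test. Works on a trapezoid grid of the smooth integrand
# a1 a2 sqrt(1 - delta1 y1^2) sqrt(1 - m(y1) sin^2 theta) (y2 = sin theta).
marginal_edges <- function(spec, k, axis = c("y1", "y2"), n_grid = 257) {
  axis <- match.arg(axis)
  y1g <- seq(spec$beta2 / spec$a1, spec$beta1 / spec$a1, length.out = n_grid)
  thg <- seq(asin(spec$alpha2), asin(spec$alpha1), length.out = n_grid)
  if (axis == "y1") { lo <- y1g[1]; hi <- y1g[n_grid]; g <- y1g }
  else { lo <- thg[1]; hi <- thg[n_grid]; g <- thg }
  if (k == 1L) return(if (axis == "y1") c(lo, hi) else sin(c(lo, hi)))
  G <- outer(sqrt(1 - spec$delta1 * y1g^2),
             rep(1, n_grid)) *
       sqrt(1 - outer(m_of_y1(spec, y1g), sin(thg)^2))
  dens <- if (axis == "y1") rowSums(G) - (G[, 1] + G[, n_grid]) / 2
          else colSums(G) - (G[1, ] + G[n_grid, ]) / 2
  cum <- c(0, cumsum((dens[-n_grid] + dens[-1]) / 2))
  q <- stats::approx(cum, g, xout = seq(0, cum[n_grid], length.out = k + 1),
                     ties = "ordered")$y
  q[1] <- lo; q[k + 1] <- hi
  if (axis == "y1") q else sin(q)
}

# factor k into a grid k1 x k2 with k1 <= k2, as square as possible
grid_dims <- function(k) {
  k1 <- floor(sqrt(k))
  while (k %% k1 != 0L) k1 <- k1 - 1L
  c(k1, k %/% k1)
}

#' Surface areas of an equal-area rectangular binning
#'
#' Partitions the rectangle domain into a `k1 x k2` grid with edges at
#' marginal area quantiles and computes each cell's true surface area by
#' quadrature.
#'
#' @param spec An [ellipsoid_patch()].
#' @param k1,k2 Grid dimensions along `y1` and `y2`.
#' @return A list with `y1_edges`, `y2_edges`, and the `k1 x k2` matrix
#'   `areas`.
#' @export
equal_area_bins <- function(spec, k1, k2) {
  stopifnot(inherits(spec, "ellipsoid_patch"), k1 >= 1, k2 >= 1)
  e1 <- marginal_edges(spec, k1, "y1")
  e2 <- marginal_edges(spec, k2, "y2")
  areas <- matrix(NA_real_, k1, k2)
  for (i in seq_len(k1)) for (j in seq_len(k2))
    areas[i, j] <- area_region_y(spec, e1[i], e1[i + 1], e2[j], e2[j + 1],
                                 rel.tol = 1e-9)
  list(y1_edges = e1, y2_edges = e2, areas = areas)
}

#' Chi-square test of surface uniformity
#'
#' Bins a sample batch on a rectangular grid in rectangle coordinates whose
#' cells have (near) equal surface area, computes expected counts
#' proportional to the cells' true areas, and returns the Pearson chi-square
#' statistic on `k - 1` degrees of freedom. Under surface uniformity the
#' statistic is asymptotically chi-square distributed; small p-values flag
#' accumulation or depletion of points.
#'
#' @param batch A `sample_batch` (or any data frame with `y1`, `y2` columns).
#' @param spec An [ellipsoid_patch()]; defaults to the batch's own spec.
#' @param k_bins Total number of cells (factored into a near-square grid).
#' @param bins Optional precomputed [equal_area_bins()] (reuse across
#'   repeated tests of the same spec).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `k_bins`, `n`.
#' @export
uniformity_chi_square <- function(batch, spec = attr(batch, "spec"),
                                  k_bins = 50, bins = NULL) {
  stopifnot(is.data.frame(batch), inherits(spec, "ellipsoid_patch"), k_bins >= 2)
  n <- nrow(batch)
  if (is.null(bins)) {
    kd <- grid_dims(as.integer(k_bins))
    bins <- equal_area_bins(spec, kd[1], kd[2])
  }
  if (n < 10 * length(bins$areas))
    stop("need n >= 10 * k_bins observations for a stable test", call. = FALSE)
  i <- findInterval(batch$y1, bins$y1_edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  j <- findInterval(batch$y2, bins$y2_edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  k1 <- length(bins$y1_edges) - 1L; k2 <- length(bins$y2_edges) - 1L
  counts <- matrix(0, k1, k2)
  tab <- table(factor(i, levels = seq_len(k1)), factor(j, levels = seq_len(k2)))
  counts[] <- as.numeric(tab)
  expected <- n * bins$areas / sum(bins$areas)
  if (any(expected < 5))
    stop("expected count below 5 in some cell; use fewer bins", call. = FALSE)
  stat <- sum((counts - expected)^2 / expected)
  df <- k1 * k2 - 1L
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 k_bins = k1 * k2, n = n)
}
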