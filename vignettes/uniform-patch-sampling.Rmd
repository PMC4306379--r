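---
title: "Surface-uniform sampling of ellipsoidal patches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-uniform sampling of ellipsoidal patches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchsampler)
```

## The problem

Curved-surface visualization of the rotator cuff asks for a surface patch
fitted to the humeral head, evaluated as a dense set of 3-D points, and
textured with gray values from an MRI volume. If the evaluation points
accumulate systematically in some regions of the patch — as lattice
evaluations of parametric surfaces do — the display resolves those regions
better than others. The package therefore treats *surface-uniform* random
generation as the core primitive: the probability that a point falls in a
region must be proportional to that region's surface area.

## The model

A patch is the graph of
$x_3 = a_3\sqrt{1-(x_1/a_1)^2-(x_2/a_2)^2}$ over a planar domain $D$ on the
upper half of an ellipsoid with semiaxes $a_1 \ge a_2 \ge a_3 > 0$. $D$ is cut
out by longitudinal bounds $\beta_2 < x_1 < \beta_1$ (lengths, $|\beta_i| \le
a_1$) and lateral bounds $\alpha_2 < x_2 / (a_2\sqrt{1-(x_1/a_1)^2}) <
\alpha_1$ (dimensionless fractions of the local half-width, $|\alpha_i| \le
1$). With the shape parameters $\delta_1 = 1-(a_3/a_1)^2$ and $\delta_2 =
1-(a_3/a_2)^2$ (so $1 > \delta_1 \ge \delta_2 \ge 0$), a planar vector $X$
whose lift is uniform on the patch has density proportional to

$$f(x_1,x_2) \propto
\sqrt{\frac{1-\delta_1 (x_1/a_1)^2-\delta_2 (x_2/a_2)^2}
           {1-(x_1/a_1)^2-(x_2/a_2)^2}},$$

the ratio of the anisotropy factor to the hemisphere area element. The
change of variables $x_1 = a_1 y_1$, $x_2 = a_2 y_2\sqrt{1-y_1^2}$ maps $D$
to the rectangle $D_g = (\beta_2/a_1,\beta_1/a_1)\times(\alpha_2,\alpha_1)$
and factorizes the transformed density whenever $\delta_2 = 0$:

* **Sphere** ($\delta_1=\delta_2=0$): $Y_1$ is uniform and
  $Y_2 = \sin(U\arcsin\alpha_1 + (1-U)\arcsin\alpha_2)$ — both marginals
  invert in closed form (`sample_sphere_inverse()`).
* **Ellipsoid of revolution** ($\delta_2=0$): $Y_2$ as on the sphere;
  $Y_1$ has density $\propto \sqrt{1-\delta_1 y_1^2}$. Rescaling
  $Z=\sqrt{\delta_1}\,Y_1$ gives the *semicircular* law, whose CDF is the
  antiderivative $\phi(t;1)=\tfrac12(t\sqrt{1-t^2}+\arcsin t)$ up to an
  affine map. $\phi^{-1}$ has no closed form; it is tabulated once and
  inverted through a monotone interpolant (`sample_revolution_inverse()`).
  Two general-purpose alternatives serve as cross-checks:
  acceptance-rejection with a uniform envelope (`sample_revolution_ar()`)
  and a random-walk Metropolis–Hastings chain.
* **General ellipsoid** ($\delta_2>0$): the coordinates are no longer
  independent, and the one-dimensional inverses would require elliptic
  integrals. The two-dimensional unnormalized density on $D_g$ is sampled
  directly by the Hastings chain (`sample_general_ellipsoid()`).

The deterministic comparators are rational triangular Bézier patches
evaluated by the weighted de Casteljau recursion and by the rational
Bernstein form; both are exact-arithmetic-identical, and the package
carries an exact degree-4 rational representation of the sphere octant.

## Tunable parameters

| parameter | where | default | why |
|---|---|---|---|
| `n_knots` | `build_phi_inverse()` | 200 | Chebyshev knots; max residual $|\phi(\hat\phi^{-1}(u);1)-u| \approx 1.9\cdot10^{-7}$, under the 1e-6 contract |
| `proposal_step` | `hastings_config()` | 0.25 × each side of $D_g$ | realized acceptance ≈ 0.5–0.7 on the shipped specs |
| `burn_in` | `hastings_config()` | 2000 | far beyond the observed relaxation of the random walk on a unit-scale rectangle |
| `thin` | `hastings_config()` | 1 | generation cost is the benchmark target; *diagnostics* thin to 10–20 (below) |
| `rel.tol` | `patch_area()` | 1e-10 | leaves ~1e-8 relative headroom for the area-additivity contract |
| `alpha`, `beta` bounds | `ellipsoid_patch()` | full upper half | octant specs (`alpha2 = beta2 = 0`) reproduce the classical benchmark configuration |

## Numerical choices

**Boundary singularity of the area element.** The surface area element in
rectangle coordinates carries the integrable factor $1/\sqrt{1-y_2^2}$,
singular where the patch reaches the equator ($|\alpha_i| = 1$). The
substitution $y_2=\sin\theta$ removes it exactly, leaving the smooth
integrand $a_1a_2\sqrt{1-\delta_1y_1^2}\sqrt{1-m(y_1)\sin^2\theta}$ that
nested adaptive quadrature handles at 1e-10 relative tolerance. The same
trick drives the equal-area binning used by the uniformity test.

**Domain edges.** The domain is treated as open, but points within 1e-12 of
the boundary are accepted by clamping: samplers and evaluators legitimately
produce exact endpoint values (e.g. $U=1$), and rejecting them would bias
nothing but break round-trips. Shape classification (`is_sphere`,
`is_revolution`) uses a relative semiaxis tolerance of 1e-12; on the
revolution branch, $\delta_1$ below that threshold delegates to the sphere
formula to avoid the $0/0$ in $Z=\sqrt{\delta_1}\,Y_1$.

**Knot placement for $\phi^{-1}$.** $\phi'(\pm1)=0$, so the inverse
steepens at the interval ends. Chebyshev-spaced abscissae cluster knots
exactly there; the residual falls monotonically with the knot count
(measured: 2.2e-5, 2.6e-6, 1.9e-7, 1.3e-8 at 50/100/200/400 knots). The
interpolant is the Fritsch–Carlson monotone cubic Hermite scheme
(`stats::splinefun(method = "monoH.FC")`), which cannot overshoot monotone
data, so the tabulated inverse is itself monotone.

**Acceptance-rejection envelope.** The uniform envelope on
$(\beta_2/a_1,\beta_1/a_1)$ gives the constant
$c = ((\beta_1-\beta_2)/a_1)\,f^*$ with $f^*$ the marginal density maximum:
its value at 0 when the interval straddles the origin, else the larger
endpoint value. The sampler loops until exactly `n` points are accepted and
records the proposal count; the expected efficiency is $1/c$ and is checked
against a 99% binomial confidence interval.

**Hastings proposals outside $D_g$** are treated as zero-density and
rejected rather than reflected — simpler, and it preserves the stationary
law exactly. The chain's stopping rule is a fixed burn-in (2000) rather
than a convergence diagnostic; this is a deliberate simplification, noted
as such, appropriate for the unimodal, box-supported targets at hand.

**Dependent draws in diagnostics.** The chi-square and Kolmogorov–Smirnov
tests assume independent samples. The Hastings chain is autocorrelated, so
the test suite thins it (by 10 for the chi-square at n = 50,000, by 20 for
two-sample KS comparisons) before testing; unthinned chains inflate both
statistics regardless of how correct the stationary law is. Thinning is a
property of the *diagnostic*, not of the sampler, whose default remains
`thin = 1`.

**De Casteljau weights** are recomputed at every level of the recursion
(the weighted-average form), not via a pre-homogenized 4-D linear
recursion; the two agree to machine precision on positive-weight patches,
and the weighted form is the one whose intermediate points stay
interpretable.

**The degree-4 sphere octant** is constructed, not stored: a rational
quadratic triangular patch maps the domain triangle onto the quarter disc
$\{p,q\ge0,\,p^2+q^2\le1\}$ (two straight edges, one standard rational
quarter-circle arc), and composing with the inverse stereographic
projection $(p,q)\mapsto(2p,2q,1-p^2-q^2)/(1+p^2+q^2)$ — also homogeneous
quadratic — yields an exact degree-4 rational patch in Bernstein form. All
15 weights come out strictly positive, and the measured on-sphere residual
is at machine precision (the contract asserts 1e-9). Ellipsoid octants
scale the control points anisotropically, which rational patches admit
exactly. Any exact degree-4 realization is acceptable; this one was chosen
because it is derivable and verifiable in a few lines of polynomial
algebra.

## What the synthetic data emulates — and what it does not

`synthetic_shoulder_volume()` builds a shoulder-like phantom: a 128³ 1 mm
grid with a spherical "humeral head" (radius 24 mm), a bright 4 mm shell on
its surface (the tendon footprint, gray 200 against background 20), and a
darker spherical cap on the shell (the partial tear, gray 60, angular
radius 0.4 rad) plus Gaussian noise (sd 5). Intensities are well separated
so that a threshold halfway between tear and shell classifies points
essentially noise-free. The designed cap fraction of the upper hemisphere
is $1-\cos\theta \approx 0.0789$; the end-to-end test samples 50,000
uniform points on a sphere patch fitted to noisy landmarks, textures them
from the phantom, and recovers this fraction within ±0.02.

The phantom is deliberately idealized: no Rician noise, bias field,
partial-volume anatomy, oblique acquisition, or motion. Passing tests
establish that the geometry, sampling and interpolation chain is correct —
not that the display would segment real MRI tears; the package proposes a
display, not a detector.

`noisy_sphere_points()` / `noisy_spheroid_points()` produce
surface-uniform landmark clouds with radial/normal Gaussian noise for the
fitting routines. Fit tolerances in the tests (center and radius within
0.1 mm at σ = 0.5 mm, n = 500; spheroid semiaxes within 0.2 mm at
n = 1000) are means over ten seeds, calibrated to the observed Monte-Carlo
spread of the algebraic estimators, which carry a small noise-induced bias
like all algebraic quadric fits.

## Problem sizes

The distributional test battery runs at the study sizes: n = 50,000 for
one-sample tests against analytic CDFs and for the equal-area chi-square
(≥ 50 cells), n = 20,000 per arm for two-sample cross-method agreement,
200 seeded repetitions for the mean-chi-square concentration check, and
100,000+ proposals for the acceptance-rate interval. The benchmark harness
uses the classical sizes 1035, 10011 and 50086 (the first two are
triangular numbers, matching full barycentric lattices at m = 44 and 140;
the third is completed with a partial last row). Statistical acceptance
thresholds are p > 0.001 with seeds fixed in the suite, chosen so that the
seeded runs are stable while any systematic nonuniformity at these sizes
fails decisively.

## Design decisions that were genuinely open

* **Axis of the revolution fit.** Nothing in a point cloud picks the
  symmetry axis of an ellipsoid of revolution without a nonlinear 9-param
  fit, which is out of scope. The caller supplies the axis (anatomically:
  the humeral shaft direction); the default is the volume z-axis.
* **Voxel convention.** 0-based indices, world = origin + index ⊙ spacing,
  `origin` at the *center* of voxel (0,0,0), interpolation domain ending at
  the outermost voxel centers with no extrapolation. Stated prominently
  because every neighboring convention (corner origins, half-voxel shifts)
  produces silently wrong textures.
* **Surface-point sampling.** Gray values are taken at the surface point
  itself; a normal offset would be a display-side choice and defaults to
  none (`texture` command).
* **Equal-area binning.** The uniformity chi-square uses a rectangular
  grid in rectangle coordinates with edges at marginal area quantiles, so
  expected counts are (near) uniform; each cell's expected count is
  computed from its *exact* quadrature area, so approximate edge placement
  cannot bias the test.
* **Benchmark aggregation.** Median of 7 repeats after one warm-up
  (overridable); timings are reported, never asserted, because they are
  hardware facts, not correctness facts.

## Known limitations

* Patches live on the *upper* half-ellipsoid; lower patches are obtainable
  by reflection but are not represented.
* Inverse-transform sampling of the general triaxial ellipsoid is not
  provided (it requires elliptic integrals); the Hastings route covers that
  case at higher cost.
* Volumes must be axis-aligned; oblique orientations must be resampled
  upstream.
* The Hastings sampler's fixed burn-in is not a convergence proof; for
  unusual patch geometries inspect the realized acceptance rate (warned
  outside (0.01, 0.99)) and thin before testing.
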