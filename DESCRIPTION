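Package: patchsampler
Title: Surface-Uniform Sampling and Deterministic Evaluation of Ellipsoidal Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating points on spherical and ellipsoidal surface
    patches fitted to anatomy, as used for curved-surface visualization of
    magnetic-resonance volumes of the shoulder. Provides surface-uniform
    random samplers (inverse transform for the sphere and the ellipsoid of
    revolution via the semicircular distribution, acceptance-rejection, and
    Metropolis-Hastings for the general ellipsoid), deterministic evaluation
    of rational triangular Bezier patches by the de Casteljau recursion and
    the Bernstein representation including an exact degree-4 sphere octant,
    least-squares fitting of spheres and ellipsoids of revolution to point
    clouds, trilinear texturing of point clouds from voxel volumes, a
    synthetic shoulder phantom generator, uniformity diagnostics, and a
    benchmark harness comparing the computational cost of the evaluators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    RNifti
Config/testthat/edition: 3
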