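---
title: "Landmark-based 3D cephalometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based 3D cephalometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephalomorph)
```

This vignette is the package's account of the science it implements: the
measurement model, the statistical procedure, the clustering and warping
machinery, the synthetic-data generator that stands in for clinical
cohorts, and the choices made where the design was genuinely open.

## The measurement model

A specimen is an ordered set of 18 named craniofacial landmarks in
millimetres (`landmark_codes()`), spanning the midface (Nasion, anterior
nasal spine, orbital and frontoorbital points) and the mandible
(Pogonion, condyles, molar root levels, posterior mandibular points).
The ordering is fixed once and used everywhere, since Procrustes methods
and thin-plate splines require point-wise correspondence.

Eight distances are defined on landmark pairs
(`distance_definitions()`): four vertical (V1 Nasion–Pogonion, V2
Nasion–SPA, V3 SPA–Pogonion, V4 FOS r–IOE r), three horizontal (H1
frontoorbital width, H2 intercondylar width, H3 inter-molar width) and
one oblique (Z1 IOE r–Co r). Eight proportions P01–P08 are ratios of
these distances (`default_proportion_spec()`); ratios are
similarity-invariant, so the proportions can be computed on raw
millimetre coordinates before any superimposition.

Two entries of the published proportion shorthand cannot be evaluated
literally, and the defaults interpret them:

* **P05** is printed against a distance code V6 that is not among the
  defined distances. V4 is the only defined vertical distance unused by
  any other proportion, and the only one that reproduces the printed
  magnitude (≈ 5); the default maps P05 → V1/V4 and flags the
  substitution in the result's `"substitutions"` attribute.
* **P07** is printed as a difference V3–H1. A literal difference is not
  scale-invariant and contradicts the dimensionless use of the
  proportions, so the default maps P07 → V3/H1. Both interpretations
  remain configurable through the proportion-definition table.

A consequence worth knowing: with all eight defaults being ratios of the
same eight distances, P07 and P08 are algebraically tied to the others
(P07 = P01/P04 and P08 = P02/P01 on any single configuration). Published
*group means* need not satisfy these identities (a mean of ratios is not
a ratio of means), which is why the synthetic calibration below treats
P01–P06 as free targets and reports the realized P07/P08.

## Procrustes superimposition

`align_pair()` solves the orthogonal-Procrustes problem with optional
uniform scale: the rotation comes from the SVD of the cross-covariance
of the centered configurations, with the smallest singular direction
sign-flipped whenever the determinant would be negative. Improper
rotations (reflections) are therefore impossible by construction — a
mirrored target is fitted by the best proper rotation and a nonzero
residual. Collinear (rank-deficient) configurations are rejected.

`gpa_mean()` computes the generalized Procrustes mean: every shape is
centered and scaled to unit centroid size, then iteratively rotated onto
the current mean, which is re-averaged and renormalized to unit centroid
size until it moves by less than `tol` (default 1e-8, in Procrustes
distance; `max_iter` 100). Design choices:

* **Scaling mode.** The default keeps every shape at unit centroid size
  and optimizes rotation only; `scale_mode = "per_iteration"` instead
  re-optimizes each shape's scale at every alignment (full-Procrustes
  scaling). On cohorts of the kind analyzed here the two means agree far
  below measurement noise; both are exposed because the convention is a
  known source of cross-package discrepancies.
* **Initial reference** is the first shape in input order; the
  pose-invariance property (the mean is unchanged, to 1e-6, when all
  inputs are re-posed by random similarity transforms) is tested, which
  guards against order sensitivity.
* **No tangent-space projection** of the aligned shapes is performed;
  all downstream statistics run on the proportions, not on Procrustes
  coordinates, so the projection would not change any reported number.
  It is noted as an extension point.

`procrustes_distance()` is the full-Procrustes residual between
unit-size configurations (symmetric by construction); it is the
convergence metric and the test metric.

## Group statistics

Per group and proportion, `ks_normality()` computes the one-sample
Kolmogorov–Smirnov statistic against a normal with the sample's own mean
and standard deviation. Estimating the parameters from the same sample
makes the plain KS p-value anticonservative (the Lilliefors effect); the
screen is implemented in this plain form because that is the procedure
the pipeline models, with `lilliefors = TRUE` (via `nortest`) available
when a calibrated p-value is wanted.

`welch_t()` performs the two-sided two-sample t-test, by default in the
Welch unequal-variance form (`var_equal = TRUE` gives the pooled
Student form). `bh_adjust()` applies the Benjamini–Hochberg step-up
adjustment. `compare_groups()` combines the three into the standard
8-row comparison table; the BH correction is applied **within** each
8-test table and never across tables, matching the structure of
separately corrected sex and per-sex cluster comparisons. Alpha defaults
to 0.05. Adjusted p-values are kept at full precision internally and
rounded to 3 decimals only in the fixed-width text rendering.

One degenerate case is handled specially: when both groups are constant
and identical in a proportion (possible only for noise-free synthetic
input), the t statistic is undefined and `welch_t()` errors;
`compare_groups()` records `raw_p = 1` for such columns so the
null-pipeline path remains runnable end to end.

## Sub-phenotype clustering

`kmeans_fit()` clusters the proportion vectors with Lloyd iterations
(via `stats::kmeans`) from k-means++ seedings, keeping the best of
`n_init = 20` restarts by total within-cluster sum of squares, all
deterministic given `seed`. Choices:

* **Feature scaling.** Proportions differ about five-fold in magnitude
  (P05 ≈ 5 versus P04 ≈ 1), so unscaled Euclidean clustering would be
  dominated by P05 alone. The default z-scores each proportion;
  `scaling = "none"` is available to probe sensitivity. Which mode was
  used is recorded in the model and the report provenance.
* **Algorithm.** Lloyd with k-means++ restarts rather than
  Hartigan–Wong; at the separation of the calibrated sub-phenotypes the
  partition is identical, and the k-means++/Lloyd combination has a
  cleaner determinism story. Rare empty-cluster events are repaired by
  reseeding the empty centroid at the farthest point.
* **Choice of k.** The elbow curve (`elbow_curve()`) is always computed
  as a diagnostic — the automated proposal is the k maximizing the
  discrete second difference of the WSS curve — but k itself is an
  explicit configuration input (default 2): cluster count is a modelling
  decision, not something to delegate silently to a heuristic.

With k = 2, `label_phenotypes()` names the cluster with the larger mean
P01 (vertical/transverse ratio) dolichofacial and the other
brachyfacial, with ties broken by mean P02.

## Thin-plate-spline template morphing

`tps_solve()` solves the standard bordered system
`[K + λI, P; Pᵀ, 0]` for an exact 3D thin-plate interpolant with kernel
U(r) = −r, the biharmonic fundamental-solution convention in 3D
morphometrics (`kernel = "r"` flips only the sign of the solved weights;
the map is identical, as a test verifies). λ defaults to 0 — pure
interpolation along the control points — with small positive values
exposed for noisy landmark placements; the bending-energy term
wᵀKw decreases monotonically in λ.

`morph_template()` adds the bridge the template workflow needs: a GPA
mean shape has unit centroid size and sits at the origin, so a TPS
straight onto it would collapse a millimetre-scale mesh. The target mean
is therefore first similarity-aligned (rotation, translation, scale) to
the template's own landmark configuration, and the TPS maps the template
landmarks onto those rescaled targets. The morph thus changes only
shape, never gross size or pose, and an exactly-similar target produces
the identity morph. Mesh topology is untouched: the face list and vertex
count pass through unchanged.

## The synthetic cohort generator

`realize_proportions()` inverts the measurement model. It fixes
H1 = `base_scale_mm` and derives V1 = P01·H1, H3 = V1/P02, H2 = V1/P03,
V3 = V1/P04, V4 = V1/P05, Z1 = V1/P06, then places the 18 landmarks on a
fixed bilaterally symmetric scaffold (midline points on the x = 0 plane,
paired points mirrored in x) in which exactly the defining pairs attain
the derived distances. The ten landmarks not pinned by the eight
distances sit at fixed scaffold positions scaled by V1 — arbitrary but
frozen, because GPA mean shapes depend on all 18 points. P07/P08 cannot
be set independently of P01–P06 (see above); the precedence
P01–P06 > P08 > P07 is fixed and realized values are reported back.
Geometrically unrealizable targets (triangle-inequality violations in
the Nasion–SPA–Pogonion triangle, a Z1 shorter than the condylar
half-width gap) raise errors rather than silently distorting.

`generate_cohort()` draws, per specimen, i.i.d. Gaussian displacement of
every coordinate plus (optionally) a Haar-uniform random rotation, a
translation within ±500 mm and a uniform scale in [0.8, 1.25].
Defaults are the study conditions the package targets: two sexes of
46/44 specimens, two clusters per sex split evenly (per-cluster sizes
are not published; an even split is this package's choice),
`base_scale_mm = 100` (a realistic adult frontoorbital width, giving
V1 ≈ 108–118 mm), and `noise_sd_mm = 0.5` — of the order of the 0.4 mm
voxel spacing of clinical CBCT, i.e. sub-voxel digitization noise, a
plausibility choice rather than a measured figure.

What the generator emulates: the group-mean proportion structure of the
published cohort, landmark-level digitization noise, and arbitrary
scanner poses. What it does not emulate: anatomical covariance between
landmarks (noise is isotropic and independent), within-group variation
of the proportions themselves beyond what landmark noise induces,
bilateral asymmetry, and any age structure. Passing tests therefore
demonstrate that the *pipeline* recovers planted structure under
realistic noise — not that real cohorts are this well separated.

The toy meshes (`generate_toy_mesh()`) are convex hulls of the landmark
cloud, optionally midpoint-subdivided, carrying the full landmark
annotation. They exercise every morphing contract (interpolation,
topology preservation, identity morphs) while making no claim to
anatomical realism.

## Numerical choices and degenerate inputs

* GPA: tolerance 1e-8 (Procrustes distance), `max_iter` 100, both
  configurable; the objective is non-increasing across iterations and
  the mean is renormalized to unit centroid size every iteration.
* Alignment and TPS reject rank-deficient inputs (collinear
  configurations, coplanar control points) with named errors; TPS
  requires ≥ 5 control points.
* Landmark validation rejects missing, duplicate, non-finite and
  exactly coincident landmarks, naming the offender; the pipeline drops
  such specimens with a logged reason and never imputes.
* k-means on an all-identical feature matrix warns and returns a single
  effective centroid; z-scoring guards zero-variance columns.
* STL import welds vertices on a 1e-6 mm grid (configurable); PLY
  polygon faces are split fan-wise; ascii PLY is written with full
  double precision, binary PLY/STL as 32-bit floats.
* All stochastic steps (cohort generation, k-means restarts) are pure
  functions of their seed; rerunning a configuration reproduces every
  output file byte for byte.

## Problem sizes used in the test suite

The suite runs cohorts at the study scale (46/44 specimens per sex,
22–23 per cluster) for the calibration-recovery and cluster-recovery
checks, 100-replicate property loops for the measurement invariants,
500 planted-signal replicates for the FDR property and 2,000 null
comparisons for the Welch type-I-rate check — sizes chosen so the whole
suite completes in well under a minute while keeping Monte-Carlo error
far below the tested tolerances.

## Known limitations

* The P05/P07 interpretations above are documented substitutions for an
  ambiguous published shorthand; alternative readings can be supplied
  via the proportion-definition table but are untested against any
  published value.
* The KS screen is anticonservative in its default form (by design, see
  above).
* The scaffold's free-landmark placement is one fixed choice among
  many; GPA mean *shapes* of synthetic cohorts are therefore
  scaffold-specific even though all proportion-level results are not.
* Meshes are transported through the TPS as vertex sets; self-
  intersection of extremely deformed surfaces is not detected.
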