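---
title: "Methods: volumetric and shape modularity of the brain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric and shape modularity of the brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavemorph)
```

## The scientific problem

Cave-adapted populations of the Mexican tetra (*Astyanax mexicanus*) have
repeatedly evolved a characteristic remodelling of the brain relative to
their surface-dwelling conspecifics: dorsal sensory territories (optic
tectum, cerebellum and neighbours) contract while ventral sensorimotor
territories (hypothalamus, subpallium) expand. Because surface and cave
morphs interbreed, F2 hybrid cohorts segregate this variation, and the
*covariation* of region volumes across F2 individuals reveals which regions
are under shared developmental control — regions that inherit together form
modules. `cavemorph` implements the full analysis chain for this study
design: atlas-based volumetrics, population comparison, covariation module
detection, 3-D geometric morphometrics of region shape, and the comparison
of shape modules with volume modules; plus a synthetic cohort generator
with known ground truth used to validate every step.

## Volumetrics

A specimen is a 3-D integer label volume (NIfTI). A region's volume is its
voxel count, expressed as a fraction of the total brain — the union of all
nonzero labels at the ontology level being analyzed. This makes volumes
*compositional*: each individual's fractions sum to 1 exactly, which by
itself induces negative correlations among fractions. The generator exposes
both raw and normalized volumes so this closure effect can be measured
(at zero planted correlation the raw log-volumes are uncorrelated while
the fractions are negatively correlated; see the package tests).

Population comparisons use a one-way fixed-effects ANOVA per region
(two-sample t when only two groups are present), with pairwise contrasts
computed on the pooled within-group mean square and corrected by the
Holm–Šídák step-down: order the m raw p values ascending and set
`adj_i = 1 - (1 - p_i)^(m - i + 1)`, enforcing monotonicity. A Welch
variant of the contrasts is available by flag. Tests are two-sided
throughout. `wildtype_volume_anova()` applies the same ANOVA directly to a
CSV of per-population normalized-volume columns, the layout in which such
measurements are usually published.

Segmentation QC uses vectorized Pearson correlation: two volumes are
flattened in identical voxel order within a mask and correlated. Per-region
concordance between an automated and a manual segmentation is the Pearson
correlation of the two binary indicator vectors over the joint brain mask;
whether published "segmentation cross-correlation" figures used binary
masks or label-weighted vectors is generally not stated, so binary masks
are the default here and a Dice coefficient is reported alongside as a
clearly secondary column.

## Covariation modules

The region × region Pearson correlation matrix across F2 individuals is
converted to the distance `d = 1 - r` and clustered agglomeratively.
Two numerical choices deserve comment:

* **`1 - r`, not `1 - |r|`.** Modules are defined by *positive*
  covariation; anticorrelated regions belong to opposing modules and must
  be distant (r = -1 maps to the maximal distance 2).
* **Average linkage, cut at 0.7 × the maximum merge height.** The linkage
  behind published cluster counts of this kind is rarely stated; average
  linkage is robust for correlation distances, and the cut height rule is
  a common dendrogram convention. Both are surfaced as arguments
  (`linkage`, `k`, `h`) and recorded in the partition object and pipeline
  report. Cluster ids are canonicalized by each cluster's smallest member
  so partitions are invariant to region input order.

To test whether two clusters behave as coherent modules we compare the
within-cluster correlation coefficients (both clusters pooled, each
unordered pair once) against the between-cluster coefficients with a Welch
two-sample t test. Published analyses of this design describe "adding up
the correlation values of the clusters and running a pairwise comparison",
which does not pin down a unique statistic; the within-versus-between
Welch t is this package's declared operationalization and is labelled as
such in its output. It reproduces the qualitative finding (strongly
positive t with very small p when between-module correlations are
negative) but printed t values from other implementations are not
reproduction targets.

Cluster territories are profiled along the dorsoventral axis as the mean
normalized voxel position (0 = dorsal, 1 = ventral) of each cluster's
member regions, and exported as a cluster-id NIfTI map. The dorsoventral
axis assignment comes from configuration (`dv_axis`, default the third
grid axis, increasing index = ventral) rather than the NIfTI affine,
because atlas orientation conventions in this literature are stated
anatomically, not in header space.

## Geometric morphometrics

Shape analysis is implemented from first principles in the package.

**GPA.** Configurations are centred, scaled to unit centroid size
(`CS = sqrt(sum of squared distances to the centroid)`), and iteratively
rotated onto the running consensus by the proper-rotation Kabsch solution;
the consensus is re-centred and re-scaled each round until its
root-sum-square change falls below 1e-10 (200 iteration cap, with a
non-convergence flag). Reflections are disallowed (`det(R) = +1`):
biological specimens share chirality, and allowing improper rotations
would superimpose mirror images silently. Scale is removed from the
coordinates but centroid sizes are always returned: allometry is retained
as an explicit regression of shape on size, never silently discarded.

**Semilandmarks.** Curve semilandmarks slide along the 1-D tangent
estimated from their neighbouring curve points; surface semilandmarks
slide in the 2-D tangent plane estimated from the 8 nearest landmarks or
from the mesh normal when a mesh is supplied. The default criterion
minimizes the squared Procrustes distance to the consensus, which has a
landmark-wise closed form (orthogonal projection of the offset onto the
tangent space) and is therefore deterministic and monotone. Sliding is
applied during the first five outer GPA iterations (configurable): tangents
are re-estimated from the current configuration, so unlimited re-sliding
would chase the moving consensus at a small plateau rather than converge;
a bounded number of sliding passes followed by pure alignment iterations
lets the consensus reach the 1e-10 tolerance. Thin-plate-
spline bending energy is available as an alternative criterion, solved
jointly from the bending-energy linear system of the consensus. One
numerical subtlety: with the 3-D kernel `U(r) = r` the upper-left block of
the inverse TPS system is *negative* semidefinite on the non-affine
subspace, so the bending energy is the negation of that quadratic form;
the package (and its tests) use the positive-semidefinite orientation.

**TPS and surface patching.** The 3-D thin-plate spline uses kernel
`U(r) = r` with an affine term; it is exact at anchors (residuals below
1e-8 of the configuration diameter) and reduces to the affine map when
anchors are affinely related. Template surface landmarks are transferred
to a specimen by TPS on the shared fixed/curve anchors and then snapped to
the specimen's triangle mesh by exact per-triangle closest-point
projection.

**PCA, PLS, Procrustes regression.** Shape PCA is the SVD of row-centred
flattened Procrustes coordinates; components are oriented
largest-loading-positive. No tangent-space projection is applied before
PCA: shape variation in these data is small, raw Procrustes residuals are
used, and this choice is stated here rather than hidden. Two-block PLS
decomposes the cross-block covariance and reports `r_pls`, the absolute
correlation of the first paired scores; the permutation null row-shuffles
the second block (which block is permuted is irrelevant under
exchangeability and fixed for determinism). Procrustes regression fits
shape on a single predictor by least squares and assesses it by residual
randomization (RRPP): reduced-model residuals are permuted, added back to
the reduced fit, and F recomputed. All permutation p values use the
`(b + 1) / (m + 1)` convention and are exactly reproducible given the
seed; the effect size Z is the plain standardization of the observed
statistic against the permutation distribution — other toolkits apply
additional undocumented transforms to Z, so printed Z values elsewhere are
not comparable targets.

**PC sign and module concordance.** A principal component's sign is
arbitrary, but the sign structure of a cross-region PC1 correlation matrix
is not. Each region's PC1 is therefore oriented to correlate non-negatively
with that region's own relative volume (ties fall back to the
largest-loading rule), and the applied flips are recorded. The oriented
PC1 matrix is then clustered with exactly the volume conventions, making
the shape partition directly comparable with the volume partition via the
adjusted Rand index. Specimens missing landmarks for any analyzed region
are dropped listwise, with the count recorded, matching the per-region
sample sizes typical of landmark datasets.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with every latent quantity retained as ground truth:

* **Inheritance.** Parental genotype scores are fixed (0 and 1), F1 = 0.5
  exactly, and F2 scores are means of `L = 8` biallelic loci
  (`Var(g) = 1/(8L) ≈ 0.0156`), giving a continuous surface-to-cave range.
  Dominance is a per-region piecewise map saturating at the dominant
  parent's value (`a = min(1, 2hg)` for `h ≥ 0.5`, mirrored below),
  additive at `h = 0.5` — the default, since region-specific dominance
  patterns vary.
* **Volumes.** Log raw volume = baseline + `delta · a(g, h)` + correlated
  noise. Volumes are log-normal (positive, multiplicative effects are the
  biological norm). The noise correlation is `rho_within = 0.6` inside a
  module and `rho_between = -0.4` across modules, with the dorsal module's
  `delta = -0.3` and the ventral module's `+0.3` encoding the
  dorsal-contraction/ventral-expansion tradeoff; `sigma = 0.15` scales the
  noise. No published effect sizes exist as volume fractions for this
  system, so these defaults were chosen once to be biologically plausible
  (10–30% volume effects, moderate module coherence) and testable, and are
  not revisited. Non-PSD correlation requests are repaired by eigenvalue
  clipping at 1e-8 with diagonal renormalization, and the repair is
  flagged in the output.
* **Phantoms.** Regions are rendered as ellipsoids in per-region boxes —
  dorsal module regions at low dorsoventral index — with voxel counts tuned
  by binary search to the individual's target fractions (within 5% for
  regions of at least 200 voxels), disjoint by construction, with the brain
  occupying 15% of a 64³ grid by default.
* **Shapes.** Each region's base configuration is a 20-point golden-spiral
  sphere lattice scaled by the cube root of volume (so centroid size is
  exactly proportional to volume^(1/3) in the noise-free case), plus the
  individual's module score times a fixed unit-norm deformation field
  (10 µm) and isotropic landmark noise (1 µm, a realistic digitizing
  error). Because regions of one module share the latent score, shape
  covaries within modules exactly as volume does.
* **QC fixtures.** `perturb_segmentation()` translates regions by bounded
  integer offsets and flips a chosen fraction of boundary voxels to a
  neighbouring label, preserving the label set, so concordance metrics can
  be validated against a monotone degradation.

The default cohort is 37 F2 individuals and 20 regions in two modules,
matching the hybrid sample size this study design typically uses. What the
generator does *not* emulate: realistic neuroanatomical geometry, imaging
intensities, registration artifacts beyond the simple perturbation model,
spatially varying landmark error, or linkage between loci. Passing
recovery tests therefore demonstrate that the analysis chain is correct
and well calibrated under its own assumptions, not that those assumptions
hold for any particular real dataset.

## Problem sizes and runtime choices

The test suite and acceptance script run everything at the scale of the
study design itself (n = 37, 20 regions, 64³ grids), with Monte-Carlo
components sized for stable assertions: 500 null datasets × 199
permutations for the permutation-test calibration (rejection rate expected
in [0.03, 0.07] at α = 0.05), 1000 null datasets for ANOVA p-value
uniformity, 10 seeds for module-recovery medians, 50 random pairs for the
Procrustes oracle, and 20 phantoms for exact-count checks. The whole suite
completes in about a minute on one CPU.

## Known limitations

* The cluster block test is an interpretation of an ambiguous published
  procedure (see above); its t values are not comparable across
  implementations.
* The height-based dendrogram cut is a convention, not an inference;
  cluster counts at fine ontology scales are sensitive to it, which is why
  `k` can be fixed explicitly.
* Mesh support is limited to ASCII OFF/PLY triangle soups; projection is
  exact but brute-force, sized for meshes of a few thousand faces.
* `run_full_pipeline()` renders one representative phantom for depth
  profiling rather than the whole cohort; per-individual rendering is
  available through `render_cohort_label_volumes()` when needed.
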