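---
title: "Street-tree segmentation from MLS point clouds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Street-tree segmentation from MLS point clouds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind `streetseg`, the assumptions it
makes, the parameters that matter, and the design decisions that were
genuinely open — the things a maintainer would want written down.

## The pipeline and its assumptions

The package segments individual roadside trees from mobile-laser-scanning
clouds in five stages: density clustering, noise filtering with a linearity
guard, footprint-overlay merging, breast-height localization with
density-valley splitting, and trunk-skeleton interference removal. The
underlying assumptions are worth stating explicitly:

* **Ground is stripped first.** Every stage treats a cluster's lowest point
  as its root collar. A simple grid-minimum filter (`remove_ground()`,
  1 m cells, 0.3 m margin) is provided as plumbing; production users will
  typically arrive with cloth-simulation-filtered clouds, which work the
  same way.
* **Stems are near-vertical and reach breast height.** Localization fits
  circles in the 1.25–1.35 m slab above the cluster root; a leaning or
  buried stem would need a different anchor.
* **Crowns return densely from the interior.** MLS crowns are volumetric
  point sets, not shells. The density-valley split and the crown-base
  estimator both rely on per-voxel point *counts*, which presumes roughly
  comparable sampling density across the trees of one scene.
* **One scene, one scale.** The noise rule (below) uses a scene-wide mean
  cluster size, so the trees of a scene should be broadly comparable —
  true of planted street rows, not of mixed natural stands.

## Stage-by-stage parameters

| key | default | unit | role |
|---|---|---|---|
| `dbscan.eps` | 0.6 | m | DBSCAN neighbourhood radius; order of MLS point spacing on crowns |
| `dbscan.min_pts` | 10 | — | core-point threshold |
| `ransac.dist_threshold` | 0.4 | m | point-to-line inlier distance for the linearity check |
| `ransac.n_iter` | 200 | — | sampled pairs (exhaustive below 50 points) |
| `noise.linear_ratio_cutoff` | 0.9 | — | inlier ratio above which a cluster counts as linear |
| `merge.containment_cutoff` | 0.9 | — | footprint containment treated as "complete overlap" |
| `skeleton.slab_height` | 0.25 | m | Z-voxel height for the trunk skeleton |
| `skeleton.radius_margin` | 0.2 | m | added to 2 × fitted stem radius for the rejection cutoff |
| `slab.lo`, `slab.hi` | 1.25, 1.35 | m | breast-height slab above the cluster root |
| `slab.linkage` | 0.35 | m | XY single-linkage gap for slab sub-clustering |
| `slab.arc_min` | 180 | ° | minimum angular coverage of an accepted stem ring |
| `slab.rms_rel` | 0.25 | — | maximum radial RMS residual / radius for a stem ring |
| `trunk.r_min`, `trunk.r_max` | 0.03, 1.5 | m | stem-radius plausibility gate |
| `split.voxel_width` | 0.5 | m | voxel size along the trunk-connection axis |

All keys are set through `seg_config()`, which validates the schema and
rejects unknown names.

The noise rule deserves a note: the threshold is one third of the mean
point count of the *nonlinear* clusters, and linear clusters are exempt
from it by default. The linearity check exists precisely so that bare
trunk fragments — small, elongated, easily mistaken for noise — survive
until the footprint merge can reunite them with their crowns; discarding
them by size would reintroduce the over-segmentation the merge is meant to
repair. Pole-like clusters that never merge with a nonlinear cluster are
dropped later, after merging, as street furniture. `exempt_linear = FALSE`
restores the strict size-only reading.

## Numerical choices

* **Circle fitting.** The Kåsa least-squares fit is linear in (A, B, C)
  and solved by the normal equations *in a centered frame*: for a 5 cm
  ring 40 m from the origin, the raw design matrix is nearly rank-2 (the
  coordinate columns are almost proportional to the intercept), and the
  fit either degrades or trips the singularity guard. Centering costs
  nothing (the estimator is translation-equivariant) and makes the fit
  exact to machine precision on noiseless circles at any offset.
  Collinearity is detected from the eigenvalues of the centered scatter
  matrix; non-positive squared radii abort with a clear error.
* **Ring validity.** A circle can be fitted through anything. Accepted
  stem fits must be ring-like: radius in `[r_min, r_max]`, radial RMS
  residual below `rms_rel` × radius, and points covering at least
  `arc_min` degrees of arc around the center (checked in 30° sectors; 180°
  tolerates one-sided scan coverage). A sign board 0.6 m from a stem fits
  a plausible 0.16 m circle — the residual and arc gates are what reject
  it. The same relative-residual gate marks `dbh()` unavailable on
  crown-only fragments, whose breast-height slab is a filled disc.
* **Quickhull.** The crown hull uses the classic farthest-point recursion
  seeded by the x-extreme points (ties broken on y), with a 1e-12 strict
  side test so collinear boundary points are not duplicated; output is
  counter-clockwise, which the convex clipping (Sutherland–Hodgman) used
  for footprint overlap and AIoU relies on. Degenerate projections
  (< 3 distinct non-collinear points) become zero-area footprints whose
  overlap falls back to a point-in-polygon fraction.
* **Density valley.** The span between adjacent stem positions is divided
  into `floor(span / voxel_width)` equal bins (width ≈ `voxel_width`); the
  boundary is the minimum-count bin's center, ties broken toward the
  midpoint, and a span shorter than two voxels falls back to the midpoint
  with a warning. Binning is one-dimensional along the rotated
  trunk-connection axis; a full 2D voxel grid would measure the same
  valley at more cost, and the 1D marginal is what the analytic crown
  mixture predicts.
* **Crown-base estimation.** The skeleton must know where the stem ends
  and foliage begins. A fixed "count jump" multiplier on the bare-stem
  slab count fails for slender crowns, whose peak slab count can sit
  *below* three times a dense stem's; instead the estimator anchors at the
  fullest slab (certainly crown) and walks downward while counts stay
  above 1.2 × the bare-stem reference (median of the lowest four occupied
  slabs). Street furniture part-way up the stem cannot capture the walk
  because clean stem slabs separate it from the crown.
* **Interference removal is evidence-gated.** Far-from-axis points are
  stripped only below the top of the *contaminated* zone: slabs whose XY
  centroid deviates more than 0.08 m from the stem axis (a symmetric stem
  or crown slab cannot deviate; a sign pulls the centroid sideways), plus
  one slab of margin. A clean tree therefore loses nothing even when the
  crown-base estimate overshoots into the sparse lower crown — stripping
  everything below an overestimated crown base was measurably eating
  crown bottoms.
* **Slab linkage 0.35 m.** Sub-clustering the breast-height slab at 0.5 m
  single linkage fuses a sign 0.6 m from the stem axis (≈ 0.45 m clear of
  the bark) with the stem ring and biases the circle fit; 0.35 m keeps
  them apart while never splitting stems, which are ≥ 3 m apart even in
  glued pairs.
* **Pipeline order.** Merging precedes localization; splitting precedes
  interference removal. The skeleton axis of a cluster holding two stems
  points nowhere useful, so interference removal runs per child after the
  split, using each child's breast-height fit center as its axis.
* **Determinism.** RANSAC is exhaustive for clusters of ≤ 50 points and
  seeded otherwise; every stochastic step takes a seed and restores the
  caller's RNG state. Same input, same configuration, same seed —
  byte-identical output.

## The synthetic generator

`simulate_scene()` builds the study conditions the pipeline is tested
under: trees in a row at 8 m spacing, stems as cylinder-surface samples
(2000 points/m²) from ground to crown base, crowns as uniform samples of
an axis-aligned ellipsoid volume (500 points/m³), isotropic Gaussian
sensor noise of 1 cm, and per-point ground-truth labels. Tree parameters
default to realistic street-tree ranges — heights 6–13 m, stem radii
0.05–0.15 m, crown radii 1.6–2.2 m, crown bases 2.5–3.5 m. Defects
reproduce the two failure modes: `glued_pair` moves two trees to 4 m
spacing with crowns inflated to overlap (one under-segmented cluster,
two stems), `trunk_gap` deletes a 1.6–2.4 m band of stem points
(a floating crown fragment). Distractors are a 0.5 × 0.05 × 1 m sign
0.6 m from a stem, a 4 cm pole, and a 1 × 0.5 × 1 m box; the optional
ground plane is a jittered z = 0 sheet at 100 points/m².

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: scanner-side occlusion (one-sided stems,
shadowed crown interiors), intensity/return-number attributes, leaning or
forked stems, non-ellipsoidal or inter-penetrating crown shapes beyond
simple overlap, understory vegetation, and terrain relief. The arc-coverage
default of 180° anticipates one-sided stems, but no test exercises them.

Scene sizes are chosen for fast, repeatable runs: the end-to-end defect
scene uses six trees (~200k points), morphometry recovery uses 20
independent trees, oracle-equivalence checks use 100 random instances of
up to 200 (clustering) and 500 (hulls) points, and conservation properties
run over 50 seeds. The defect scene uses a homogeneous stand (9–12 m):
with very heterogeneous heights, a glued pair of tall trees inflates the
scene-mean cluster size enough that a small tree's crown fragment falls
below the one-third noise threshold — that is the documented behaviour of
the size rule on small mixed scenes, not a target of the defect test.

## Known limitations

* The one-third noise rule is scene-global; in scenes mixing very large
  and very small trees it can discard small crown fragments (see above).
* Stems shorter than ~1.35 m above the cluster root, or clusters whose
  slab holds no ring (heavy occlusion at breast height), cannot be
  localized and are returned to noise rather than guessed.
* The trunk-radius gate's upper bound (1.5 m) and the street-furniture
  assumptions (furniture below crown base, ≤ ~3 m tall) are urban
  defaults; both are configurable.
* Crown metrics use the convex hull, so concave crowns are over-estimated
  by construction; crown area is reported as the hull's shoelace area.
* LAS support covers version 1.2, point format 0, ASCII PLY only; labels
  in LAS ride in the point_source_id field (read back signed).
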