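---
title: "Methods: 3D morphometrics of microcarrier beads from micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometrics of microcarrier beads from micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microcarriers are 100–300 µm beads used as attachment substrate for
adherent cells in stirred bioreactors. Their function depends on geometry:
total and *accessible* surface area, porosity, size distribution, and the
hydration-driven swelling between dry and wet state. Contrast-enhanced
micro-CT can image hydrated beads in 3D at a few µm resolution, but turning
such volumes into per-bead numbers requires a pipeline: staining-aware
binarization, isolation of individual beads that touch each other, and
per-bead 3D morphometrics. `beadct` implements that pipeline for two bead
families:

* **spherical beads** (e.g. polystyrene or dextran carriers), detected
  directly by a 3D spherical Hough transform;
* **non-spherical, porous or concave beads** (e.g. gelatin macro-porous
  carriers), isolated by a six-step pore-sealing / watershed algorithm and
  measured by convex-hull pore decomposition.

Because raw CT volumes of this kind are rarely shareable, the package
treats a synthetic phantom generator as a first-class module: every stage
can be validated against exhaustive voxel ground truth.

## Scene model and binarization

A stained micro-CT scene has three intensity phases: air, liquid
(buffer/contrast agent) and bead matrix, giving a three-mode histogram (two
background peaks, one bead peak). Binarization is a 3-class Otsu split:
the two thresholds maximizing the between-class variance are found by
exhaustive search over all threshold pairs (native integer bins for 8-bit
data; 256 equal-width bins otherwise), so the optimum is exact and the
boundary convention is fixed: gray `g` belongs to the upper class of a
threshold `t` iff `g > t`.

The staining regime decides which class is bead:

* *positive staining* — the contrast agent stains the bead matrix, the bead
  is the brightest phase: foreground is `g > t_high`;
* *negative staining* — the agent contrasts the liquid and is excluded by
  the bead, so the bead is the middle class: `t_low < g <= t_high`.

Unweighted Otsu assumes the three classes carry comparable histogram mass.
When the bead phase is a fraction of a percent of the voxels (a nearly
empty field of view), the criterion can prefer splitting a broad background
peak instead of isolating the tiny bead mode. Real samples are densely
packed, and the phantom defaults emulate that; the limitation is worth
knowing when analysing sparse scenes.

## Spherical beads: Hough detection

Edges are voxels whose gradient magnitude exceeds `edge_threshold` (default
0.3) of the maximum. Each edge voxel votes along ± its gradient direction
at all radii in `[R_min, R_max]` (voting both ways makes the detector
agnostic to contrast polarity). Candidate centers are local maxima of the
lightly smoothed accumulator, pruned by greedy non-maximum suppression at
`min_center_separation` (default `R_min` — two beads cannot be closer than
that). For each candidate the radius is re-estimated from the edge-voxel
distance histogram, iterating center (shell centroid) and radius
(gradient-magnitude-weighted mean edge distance, which centers the estimate
on the intensity step). The detection score is the supporting shell count
normalized by the theoretical full shell `4πr²`; detections below
`accumulator_threshold` (default 0.5 — at least half the shell must be
supported) are dropped. Detection runs on a block-mean downsampled grid
(default factor 2) for speed; all outputs are µm on the original grid.

`R_min`/`R_max` are per-dataset configuration (from the manufacturer's size
range); there are no universal defaults. Per-sphere surface and volume use
the closed forms `4πR²` and `(4/3)πR³`; fitted spheres can be rendered as
10 µm-thick binary shells for visual QC overlays.

## Non-spherical beads: the six-step pipeline

Given the binarized foreground (Step 1 above):

2. **Noise removal** — 18-connected components smaller than `V_small` µm³
   are removed (MASK1).
3. **Pore disconnection** — the Euclidean distance transform of the
   background is thresholded at `R_p` (half the pore-throat thickness):
   background farther than `R_p` from any bead is "far background" (MASK2);
   pore interiors, which are everywhere within `R_p` of bead matrix, drop
   out and are thereby disconnected from the exterior.
4. **Opening** — MASK2 is morphologically opened with a ball of radius
   `R_op`, cutting residual thin connections into larger pores (MASK3).
5. **Pore clearing** — background components of MASK3 not connected to the
   volume border are isolated pores; they are removed (AND with their
   complement), and the remaining true background is dilated by `R_p` back
   to the bead boundary (MASK4). The complement of MASK4 is the sealed
   beads.
6. **Watershed** — the Euclidean distance transform of the sealed mask is
   smoothed with a 3D Gaussian (σ = 7 voxels by default, applied on the
   working grid) and its negation flooded by a marker-free priority-flood
   watershed restricted to the foreground; each catchment basin is one
   bead.

For **non-porous beads under negative staining** the pore steps (3 and 5)
are skipped; instead the mask is closed with a ball of radius `R_cl` and
small enclosed background pockets ("black volumes", default cutoff
`V_small`) are filled, both to remove speckle noise that negative staining
produces inside the bead silhouette.

Numerical choices worth pinning down:

* Ball structuring elements are exact Euclidean balls
  `{voxels with center distance ≤ r}`, implemented by thresholding the
  exact (Felzenszwalb–Huttenlocher) squared distance transform, so
  morphology is brute-force checkable.
* Watershed determinism: minima plateaus are detected explicitly; flooding
  uses a priority queue with insertion-order tie-breaking, so reruns give
  identical labels. Voxels where basins meet are absorbed by the basin
  reaching them first, so no foreground voxel is left unlabelled (beads
  must stay solid objects for morphometrics).
* Object connectivity is 18 (the pipeline's convention); background
  clearing (`imclearborder`-style operations) uses full 26-connectivity,
  matching the default of the tooling this algorithm family comes from.
* After the watershed, labels are restricted back to the binarized bead
  image: per-bead morphometrics must see the pores, which the sealing
  deliberately filled. In the non-porous variant the closed mask *is* the
  bead (the pockets it fills are staining noise, not pore space).
* Beads touching the volume border are flagged and excluded from cohort
  statistics by default — their morphometrics are truncated by the field
  of view.

`V_small`, `R_p`, `R_op`, `R_cl` are per-dataset configuration. Choosing
`R_p` trades off sealing (throats below `R_p` seal) against erosion of true
concavities; `R_p` above the largest pore-throat radius and below the bead
radius is the working regime, and the phantom tests exercise both sides of
it.

## Per-bead morphometrics

For one bead image `I` (cropped with background padding):

* closed pores `I_cl`: background components of `¬I` not connected to the
  crop border; filled bead `I_fill = I ∨ I_cl`;
* convex hull image `I_conv`: voxel centers inside the exact quickhull
  polytope of the bead's surface voxel centers (the hull is additionally
  OR-ed with `I_fill` so the conservation identity below can never be
  broken by digitization);
* open pores `I_op = I_conv ∧ ¬I_fill`.

Voxel counts give `V_conv = V_bead + V_open + V_closed` exactly, porosity
`P = 1 − V_bead/V_conv`, equivalent diameter `(6V/π)^{1/3}`, and principal
axis lengths `L_k = 2√(5λ_k)` from the eigenvalues of the voxel-coordinate
covariance with the per-voxel `1/12` moment correction (the ellipsoid with
the same normalized second central moments). For macro-porous carriers the
size/shape metrics are computed on the hull image (the "envelope" of the
bead, the convention for such carriers); for non-porous carriers on the
bead mask itself. Both supports are available via an argument; the CSV
documents the variant used.

Surface areas come from two estimators, deliberately independent:

* **Crofton intercept counts** — 13 systematic directions (3 axis, 6 face
  diagonal, 4 body diagonal) with the classical direction weights;
  `S = 4h² Σ_k c_k n_k/|d_k|`. Exact in expectation for spheres; its worst
  case is an axis-aligned cube, where it settles near −8% — the phantom
  suite pins both behaviors.
* **Convex hull facet area** — exact triangulated area of the hull
  polytope.

## Accessible surface and the probe-radius sweep

The accessible area for a cell of a given size is computed as an alpha-hull
sweep: the alpha-hull of a solid with probe radius `r` is the complement of
the union of all radius-`r` balls avoiding the solid. For a voxel solid
this is exactly the morphological closing by the Euclidean ball of radius
`r`, which is how the package computes it (no Delaunay complex is needed on
a dense voxel solid); the boundary area of the closing is measured by the
Crofton estimator. An infinite probe returns the convex surface area,
reported as the exact hull facet area — so the `+∞` entry and the Crofton
area of the hull image cross-check two genuinely different computations,
and agreement within a few percent is the expected digitization spread.

The standard sweep uses probe radii `[2, 3, 4, 10, 15, 20, 25, 38, 50, +∞]`
voxels; at 2 µm voxels these correspond to cell sizes
`[4, 6, 8, 20, 30, 40, 50, 76, 100, +∞]` µm (`cell_size_um()` reproduces
this pairing: cell size = probe radius in voxels × voxel size). Small
probes enter pores and channels, so the profile typically decreases toward
the convex limit; monotonicity is checked per phantom bead, not claimed
universally.

## Cohort statistics

* Boxplot summaries use quantiles by linear interpolation of order
  statistics at probabilities `(k − 0.5)/n` (R's `type = 5`, the convention
  of the original analysis environment for these data). Outliers are values
  beyond `q1 − 1.5·IQR` / `q3 + 1.5·IQR`; whiskers are the extreme
  non-outlier values. Any plot-side clipping of extreme outliers is a
  display concern; summaries always carry true values.
* Swelling is the percent change of a central measure (median by default,
  mean available) of the same metric between dry and wet cohorts.
* Surface per dry weight: non-swelling beads use `S̃/(Ṽ·d)` (median
  surface, median volume, material density), converted to cm²/g; for
  swelling beads the dry volume no longer relates to the wet surface, so
  the estimate is median wet surface × beads per gram dry weight, the
  count either given (manufacturer) or estimated as imaged beads over
  sample weight.
* Group comparison uses the unpaired equal-variance Student's t-test:
  pooled distributions of unequal size cannot be paired, so the unpaired
  test is the default and a paired variant sits behind a flag. Zero-variance
  degeneracy is handled by convention (equal means → p = 1).
* The normality check is a one-sample Kolmogorov–Smirnov test of the
  z-scored sample against the standard normal. Testing raw morphometrics
  against the *standard* normal would reject for location/scale reasons
  alone, so the z-scoring turns it into a shape check; this interpretation
  is a documented choice.

## The validation harness

`validate_segmentation()` scores a segmentation against a reference
labelling the way a manual-vs-automatic comparison is done: per-bead
records for every label on both sides, pooled-distribution comparison per
morphometric (mean, SD, quartiles, t-test) with no bead matching, and the
bead count error `100(n_ref − n_test)/n_ref`, rounded to the nearest
integer percent for the headline (full precision retained). For phantom
work, `match_labels()` additionally provides greedy one-to-one
IoU matching against ground truth.

## What the phantom generator emulates — and what it does not

The generator builds a scene of beads suspended in liquid inside a
cylindrical container surrounded by air, rendering the three-phase
histogram with additive Gaussian noise (8-bit range; default σ = 8 gray
levels at phase separations of 90, a realistic contrast-to-noise regime for
stained micro-CT at 2 µm voxels). Spheres have exact center/radius truth;
porous beads are randomized ellipsoids (axis ratios in `[0.6, 1]`, matching
near-spherical macro-porous carriers) carved with interior cavities and
surface channels, with truth pore volumes established by
connected-component analysis of the clean label volume. Placement is
per-bead rejection sampling (10,000 retries) on a deterministic per-bead
RNG stream, so adding beads never perturbs earlier ones and identical
spec+seed reproduces volumes bit-for-bit.

Not emulated: partial-volume blur at phase boundaries, beam hardening,
ring/streak artifacts, intensity inhomogeneity, and deformable contact
between touching beads. Passing the phantom suite therefore demonstrates
the correctness of the algorithms under the stated image-formation model,
not robustness to every scanner artifact; on real data the documented
parameters (`V_small`, `R_p`, `R_op`, `R_cl`, radius bounds) absorb much of
that gap, which is why they are per-dataset configuration.

## Problem sizes used by the test and acceptance suites

The suites exercise full-scale scenes of 256³ voxels (5-sphere Hough
recovery; 50-bead porous segmentation) and batches of 200+ smaller beads at
160³ for the conservation and porosity properties; statistical checks use
1,000 replicates. These sizes make the whole suite run in a few minutes on
one core while keeping the beads at the study's voxel-per-bead scale
(radii of 12–40 voxels).

## Known limitations

* Unweighted 3-class Otsu mis-splits nearly empty fields of view (see
  above).
* The Crofton estimator's directional bias (−8% on axis-aligned cubes) is
  inherited by all area outputs on very blocky objects.
* The watershed with a fixed smoothing σ can split strongly elongated
  beads or merge beads joined by necks wider than the smoothing scale —
  the mechanism behind the count underestimation that motivates the
  validation harness.
* Anisotropic voxels, DICOM/proprietary formats, and GPU execution are out
  of scope.
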