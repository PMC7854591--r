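# beadct — 3D morphometrics of microcarrier beads from micro-CT

Microcarriers are 100–300 µm beads used as the attachment substrate for
adherent cells in stirred bioreactor culture; how well they work depends on
geometry — size distribution, porosity, swelling, and the surface area a
cell of a given size can actually reach. Contrast-enhanced micro-CT images
hydrated beads in 3D at micrometre resolution, and `beadct` turns such
volumes into per-bead numbers and cohort statistics. It is written for
bioprocess and biomaterials groups characterizing commercial or in-house
carriers, and for image-analysis developers who need a tested, ground-truth
validated reference pipeline.

## What it computes

**Spherical beads.** A 3D spherical Hough transform (gradient-direction
voting over a radius range *[R*<sub>min</sub>, *R*<sub>max</sub>*]*) finds
centers and radii; per bead, surface and volume follow the closed forms
4π*R*² and (4/3)π*R*³. Fits can be rendered as 10 µm binary shells for
visual QC.

**Porous / concave beads.** A six-step pipeline isolates individual beads:
3-class Otsu binarization with staining-aware foreground selection
(positive staining → brightest class; negative staining → middle class),
removal of objects below *V*<sub>small</sub>, pore sealing (background
distance transform thresholded at *R*<sub>p</sub>, opening with radius
*R*<sub>op</sub>, border-clearing, dilation back by *R*<sub>p</sub>), and
marker-free watershed of the Gaussian-smoothed (σ = 7 voxels) distance
transform. A variant for non-porous beads under negative staining replaces
the pore steps by a closing with radius *R*<sub>cl</sub> plus removal of
small dark pockets.

**Per-bead morphometrics.** Convex-hull pore decomposition
(*I*<sub>conv</sub>, *I*<sub>cl</sub>, *I*<sub>fill</sub>,
*I*<sub>op</sub>) with the exact identity
*V*<sub>conv</sub> = *V*<sub>bead</sub> + *V*<sub>op</sub> + *V*<sub>cl</sub>;
porosity *P* = 1 − *V*<sub>bead</sub>/*V*<sub>conv</sub>; equivalent
diameter (6*V*/π)^(1/3); principal axis lengths 2√(5λ<sub>k</sub>) from
second central moments; Crofton 13-direction surface area; and the
accessible-surface profile — the alpha-hull of the bead computed for probe
radii [2, 3, 4, 10, 15, 20, 25, 38, 50, +∞] voxels (cell sizes
[4, …, 100, +∞] µm at 2 µm voxels), where +∞ returns the convex surface
area.

**Cohort statistics and validation.** Boxplot summaries with the
1.5·IQR outlier rule, dry-vs-wet swelling (percent change of the median),
surface area per gram dry weight, Student's t-test and one-sample KS
normality check, plus a harness that scores a segmentation against a
reference labelling (pooled per-metric comparison and the percent bead
count error).

**Phantoms.** Because raw CT volumes of this kind are rarely available,
the package includes a synthetic scene generator (spheres or carved
ellipsoids in a liquid-filled tube, three-phase histogram, Gaussian noise,
positive/negative staining) with exhaustive voxel ground truth. All tests
and the acceptance script run against these phantoms.

## Worked example

Generate a porous-bead phantom, segment it, and measure every bead:

```r
library(beadct)

spec <- phantom_spec(c(140, 140, 140), n_beads = 6,
                     radius_range = c(26, 36), bead_kind = "porous_blob",
                     pore_spec = list(n_closed = 2,
                                      closed_radius_range = c(6, 10),
                                      n_open = 2,
                                      open_radius_range = c(3, 5)),
                     min_gap = 2, staining = "positive", seed = 3)
ph <- gen_porous_bead_pack(spec)
ph$volume
#> <vol3d> 140 x 140 x 140 voxels, 2 um/voxel
#>   gray range [0, 233]  (phantom(positive))

pars <- segmentation_params(v_small = 500, r_p = 7, r_op = 5,
                            variant = "porous")
labels <- segment_beads(ph$volume, pars, "positive")
labels
#> <labelvol3d> 140 x 140 x 140 voxels, 2 um/voxel, 6 beads

rec <- bead_morphometrics(labels, "porous", probe_radii_vox = c(2, 10, Inf))
rec[, c("bead_id", "equivalent_diameter_um", "porosity",
        "convex_surface_area_um2", "alpha_area_um2_at_4",
        "alpha_area_um2_at_Inf")]
#>   bead_id equivalent_diameter_um porosity convex_surface_area_um2
#> 1       1                  54.70  0.04191                    9663
#> 2       2                  49.76  0.08009                    7796
#> 3       3                  47.73  0.08138                    7210
#> 4       4                  55.21  0.06546                    9743
#> 5       5                  49.08  0.11815                    7619
#> 6       6                  51.69  0.10010                    8507
#>   alpha_area_um2_at_4 alpha_area_um2_at_Inf
#> 1               10592                  9424
#> 2                9142                  7582
#> 3                8593                  7001
#> 4               11198                  9515
#> 5                9594                  7392
#> 6               10642                  8282

boxplot_summary(rec$equivalent_diameter_um)
#> <boxplot_summary> n = 6, mean = 51.36, median = 50.73 [q1 49.08, q3 54.7], 0 outliers

median(rec$alpha_area_um2_at_4 / rec$alpha_area_um2_at_Inf)
#> [1] 1.22
```

Reading the output: the six beads are recovered with porosities between
0.04 and 0.12 (these phantom beads carry two cavities and two surface
channels each); the accessible area seen by a 4 µm probe exceeds the
convex surface (the +∞ column) by a factor ~1.2, because small probes can
enter the open channels. `write_morphometrics(rec, "beads.csv")` exports
the full table with a stable column schema.

A thin command-line front end for shell use is installed under
`inst/cli/beadct.R` (subcommands `phantom`, `binarize`, `spheres`,
`segment`, `summarize`, `validate`).

## Documentation

The methods vignette
(`vignettes/bead-morphometrics-methods.Rmd`) describes the scene model,
every algorithm step with its parameters and units, the numerical
conventions (connectivity, quantile type, structuring elements, watershed
tie-breaking), what the phantom generator does and does not emulate, and
known limitations.
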