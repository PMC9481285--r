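---
title: "Methods: point-cloud phenotyping of maize seedlings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-cloud phenotyping of maize seedlings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedling3d)
```

## The measurement problem

A potted maize seedling filmed from many viewpoints can be reconstructed as
a dense colored point cloud by structure-from-motion plus multi-view stereo.
That reconstruction is the input this package assumes; the reconstruction
itself is out of scope. Three obstacles stand between the raw cloud and
usable phenotypes:

* the scene contains large non-plant structures (table, pot, calibration
  checkerboard) and scattered white speckle along leaf edges;
* coordinates are in arbitrary model units, with no guaranteed orientation;
* the phenotypes of interest (plant height, stem height, per-leaf length,
  width and relative area, leaf count) are defined on organs, so the plant
  must be split into stem and individual leaves.

The pipeline answers these in order: Euclidean clustering → plant-cluster
selection → color filtering → voxel downsampling → metric scaling →
growth-axis alignment → height and stem measurement → region-growing
segmentation → per-leaf measurement.

## Stage models and parameters

### Euclidean clustering

Clusters are the connected components of the graph joining every pair of
points within `distance_threshold`. The implementation flood-fills with
KD-tree fixed-radius queries; the result is provably identical to
brute-force connected components, and the test suite checks that equivalence
on randomized scenes. The default threshold is **2× the cloud's median
nearest-neighbor spacing**: scale-free, tight enough to cut the
centimetre-scale gaps between plant and furniture, loose enough to bridge
sampling irregularity. `min_cluster_size` defaults to 50 points to discard
stray specks. The plant cluster is then chosen as the one with the highest
fraction of filter-passing (green) points — not the largest, since the
table often outnumbers the seedling — with ties broken by size.

### Color filtering

For channel values $r, g, b \in [0, 255]$:

$$S_{rgb} = r+g+b,\quad abs_{rg} = |r-g|,\quad abs_{bg} = |b-g|,\quad
R_{rg} = abs_{rg}/S_{rgb},\quad R_{bg} = abs_{bg}/S_{rgb}$$

A point is kept iff every quantity falls in its empirical green range —
$S_{rgb} \in [165, 642]$, $abs_{rg} \in [35, 255]$, $abs_{bg} \in [16, 255]$,
$R_{rg} \in [0.098, 0.697]$, $R_{bg} \in [0.032, 0.670]$ — and $g > r$,
$g > b$. White edge noise fails the $S_{rgb}$ ceiling; grey surfaces fail
$abs_{rg}$ and g-dominance; soil and terracotta fail g-dominance. Two
choices need stating: $|r-b|$ and its ratio are computed but carry no range
(no empirical bounds exist for them), so they never reject a point; and a
pure-black point ($S_{rgb}=0$) is rejected outright rather than letting the
ratios divide by zero.

### Voxel downsampling

Cubes of edge `leaf_size` are anchored at the cloud's minimum corner with
half-open intervals, so a point exactly on a boundary deterministically
belongs to the higher-index voxel. Each occupied voxel is replaced by the
arithmetic mean of its member positions; colors are channel means rounded
half-up (base R's `round()` is half-to-even, which would make the many
`x.5` means produced by integer colors platform-lore rather than policy).

### Scale and alignment

A checkerboard of 25 mm squares placed in the scene gives
$k = L_{real}/L_{virtual}$; the user supplies $L_{virtual}$ (e.g. picked in
a viewer — automatic checkerboard detection is out of scope), and
`apply_scale()` multiplies all coordinates by $k$.

Alignment maps the growth axis to +z. The obvious estimator — the largest
principal component of the plant — is **not** used by default: on a leafy
seedling the leaves hold most of the points, and the dominant PC often runs
along the leaf axis, which misaligns the plant by tens of degrees and
corrupts the height. Instead the stalk axis is found directly: a
fixed-budget RANSAC line search (300 iterations, inlier tolerance 2.5% of
the bounding-box diagonal) whose candidates are locally optimized —
total-least-squares refits on the consensus set and on a 2×-widened band,
recounted at the original tolerance — so that a sample pair lying on the
stalk *surface* can snap to the stalk *axis*. The winner is polished by
refitting on all points within 1.3× the 25th-percentile distance of the
current axis, an absolute band wide enough to hold the whole stalk
cross-section and therefore unbiased, unlike a fixed-quantile trim which
keeps a diagonal slab. On generated plants this recovers the stem axis to
well under a degree, which the test suite asserts at 1°. The adaptive
stopping rule used for ordinary stem fitting is deliberately *not* used
here: it assumes any two inliers determine the model, which is false for a
thick cylinder, so it quits before the axis basin is found. Axis sign is
disambiguated by placing the half of the plant with greater x–y spread (the
leafy canopy) at +z; plain PCA remains available as `method = "pca"`.

### Plant height, stem fit, leaf measurement

Plant height is $h = z_{max} - z_{min}$ of the aligned, scaled plant.
The stalk is fit with RANSAC (minimal sample $n = 2$, confidence
$P = 0.99$, so the iteration floor is
$\lceil \ln(1-P)/\ln(1-1/n) \rceil = 7$); the running bound adapts as
$M = \ln(1-P)/\ln(1-w^n)$ with $w$ the best inlier fraction, floored at 7
and capped at 10 000. The default inlier tolerance is 1.5× the median
nearest-neighbor spacing of the candidate points. Stem height is the
distance between the extreme inlier projections on the refined line. In the
full pipeline the candidate points are the classified stem region when one
exists, else the points below the lowest leaf region, else the whole plant.

Leaf length is the straight chord between the two longitudinal extreme
points, width the distance between the transverse extreme pair, and
relative area their product. This chord convention understates arc length
on curled leaves — an accepted bias at the seedling stage, where curl is
mild. Extreme points can be supplied manually (mirroring interactive
picking) or found automatically: the tip pair is the most distant pair of
leaf points; the width pair is the extreme pair along the direction
orthogonal to the chord within the leaf's best-fit plane. On a bowed leaf
the automatic width direction absorbs some bow depth and can overshoot the
true flat width by 10–25%; supplied picks carry no such bias.

### Region growing

Per-point geometry comes from the covariance of the `k_neighbors = 30`
nearest neighbors: normal = smallest-eigenvalue eigenvector, curvature =
$\lambda_{min}/(\lambda_1+\lambda_2+\lambda_3)$ (0 on a plane, ≤ 1/3).
Growth starts at the globally lowest-curvature unassigned point; a
neighbor joins the region when the angle between its normal and the current
seed's (sign-invariant, $\cos\theta = |n_1\!\cdot\!n_2|$) is within
`angle_threshold` (default 10°), and it becomes a seed itself only when its
curvature differs from the current seed's by at most `curvature_threshold`
(default 0.05). The join-without-seeding rule matters: crease points may be
absorbed but cannot propagate growth across an organ boundary. Curvature is
compared against the *current* seed rather than the region's founding seed
(`curvature_mode = "difference"`); an absolute mode is provided because the
informal description of this family of algorithms is ambiguous between the
two. Regions under `min_region_size = 50` points are marked unassigned.
After growth, each region is RANSAC-line-fitted with a tolerance of 8% of
its extent (wide enough to swallow a stalk cross-section); among regions
whose fitted line lies within 30° of +z, the one with the highest inlier
fraction is the stem, the rest are leaves. A lone region must be decisively
line-like (inlier fraction > 0.9) to be called a stem.

One practical note on thresholds: on noiseless planes meeting at a crease,
neighborhood-blended normals rotate *gradually* across the crease, so an
angle threshold alone can never stop growth — the curvature gate does. The
two-plane oracle tests therefore run with a curvature threshold (0.005)
strict relative to the zero curvature of clean planes, while the plant
default (0.05) sits above the baseline curvature that positional jitter
induces on real and simulated surfaces.

## The synthetic scene generator

The generator is the package's test bed and ships as first-class code. It
emulates, with exact ground truth:

* a **stalk**: a structured cylindrical grid, default 90 mm × 5 mm radius;
* **2–8 leaves**: quadratic-Bezier ribbons attached at distinct heights
  (≥ 15% of stem length apart), with a parabolic width profile maximal at
  mid-leaf, alternate (distichous) azimuths, elevations drawn from
  U(35°, 55°) and sorted so the youngest (topmost) leaves are most erect —
  the habit of a real seedling, which also keeps same-side leaves from
  intersecting; default chords U(60, 140) mm, widths U(10, 16) mm, bow
  height 12% of chord;
* **surface sampling** at 2 points/mm² with 0.12 mm Gaussian jitter,
  matching the density-after-downsampling regime of MVS clouds; the four
  extreme points of every leaf are injected unjittered so recorded tip and
  width pairs are exact;
* **colors** drawn from r∼U(40,90), g∼U(120,200), b∼U(20,80) and
  rejection-sampled against the default thresholds, so plant points pass
  the filter by construction;
* **white edge noise**: a chosen fraction of plant count, channels in
  230–255, displaced ≤ 2 mm from leaf-boundary points;
* **background**: table plane, pot shell and a 25 mm-square checkerboard,
  all in colors that fail the filter and all separated from the plant by
  far more than the clustering threshold;
* an overall `k_scale` dividing coordinates into model units, so the scene
  arrives unscaled exactly as a photogrammetric model would.

What it does **not** emulate: reconstruction holes and drift, occlusion
shadows, soil clinging to the stalk base, touching or wrapped leaves,
multi-plant scenes. Passing the recovery tests therefore demonstrates the
pipeline's correctness on clean, well-separated geometry — not robustness
to every pathology of field reconstructions.

## Evaluation conventions

Absolute error is $|measured - reference|$ with the manual value as
reference; relative error is its percentage of the reference. Table output
rounds half-away-from-zero at 2 decimals (the convention of printed error
tables); all computation is unrounded. `agreement_stats()` regresses
measured on reference by OLS and reports $R^2 = 1 - SS_{res}/SS_{tot}$;
RMSE is computed on the paired differences,
$\sqrt{\mathrm{mean}((measured-reference)^2)}$, so it shares units with the
error table (the regression-residual RMSE is also reported, as the two
definitions coexist in the literature and reported values rarely say which
was used). A 15-plant manual-vs-cloud measurement table is bundled for
validation; the larger samples behind published R²/RMSE figures for this
kind of pipeline are generally unpublished, so the statistics functions are
validated by oracle equivalence (hand-written normal equations) and by
consistency checks on the bundled pairs.

## Numerical choices and determinism

* k-nearest-neighbor ties break by ascending point index; radius queries
  are closed balls.
* Voxel binning is half-open from the minimum corner; voxel colors round
  half-up.
* All RANSAC entry points take a `seed` and restore the RNG state, so
  identical inputs give identical outputs; the pipeline threads one master
  seed through every stochastic stage.
* Region growing re-polls the lowest remaining curvature for every new
  region, and processes neighbors in index order — fully deterministic.
* Eigen-decompositions use symmetric solvers; tiny negative eigenvalues
  from degenerate neighborhoods are clamped to zero.
* ASCII PLY only; binary PLY is rejected with a clear error. Colors are
  integers; float colors in [0, 1] are rejected rather than silently
  rescaled.

## Problem sizes

The shipped tests run on scenes of roughly 10 000–30 000 points (plants
sampled at 2 points/mm² plus coarser background), with oracle-equivalence
suites on 100–500-point random clouds; the acceptance script measures
recovery on 5 generated scenes per run. These sizes exercise every code
path at interactive runtimes; all stages scale near-linearly with point
count except the exact pairwise leaf-diameter search, which is quadratic in
leaf size and intended for organ-scale point sets.

## Known limitations

* Chord-based leaf length ignores curl; automatic width picks overshoot on
  strongly bowed leaves.
* Stem height on a real plant includes the region hidden by the lowest
  leaf collar; the RANSAC endpoints measure only the visible line support.
* The stem/leaf classifier assumes one stalk within 30° of vertical after
  alignment; lodged plants need the `max_tilt` parameter relaxed.
* Scale calibration trusts a single user-measured checkerboard edge;
  averaging several edges would reduce picking error.
* No temporal linking across growth stages and no multi-plant scenes.
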