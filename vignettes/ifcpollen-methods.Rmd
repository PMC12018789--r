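---
title: "Methods: pollen morphometry from brightfield object galleries"
author: "ifcpollen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollen morphometry from brightfield object galleries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifcpollen)
```

## The measurement model

An imaging flow cytometer photographs one particle per frame in transmitted
light: the grain absorbs, so it appears as a dark silhouette on a bright
background. `ifcpollen` models such a frame as

> ideal binary silhouette → multiply by contrast, subtract from background →
> isotropic Gaussian blur (the point-spread proxy) → additive Gaussian
> noise, clipped to [0, 1].

Everything downstream — masking, features, gating — assumes only this
qualitative structure: a single dominant dark object, an object-free frame
margin, and an approximately symmetric edge-spread. The pipeline makes no
assumption about pollen texture (pori, sculpture), which enters at most as
noise.

### Masking

The **object mask** is Otsu's threshold on the Gaussian-smoothed
(σ = 1 px) contrast map |I − background|, where the background is the
median of a 3-px border frame and the robust contrast scale is the 99th
percentile of |I − background| over the frame. We keep the largest
8-connected component and fill holes. Otsu needs a bimodal histogram,
which single-object frames with an object-free margin guarantee.

The **adaptive-erode mask** AE(OM, t) refines the object mask for size
measurement: within the filled 1-px dilation of the object mask, keep the
pixels whose normalized contrast c(p) = |I(p) − background| / scale reaches
the level (100 − t)/10 (clipped to [0, 1]), then take the connected
component at the object centroid and fill holes. Two properties drove this
construction:

* **Monotone nesting.** The level falls as t rises, so
  t₁ ≤ t₂ ⇒ AE(t₁) ⊆ AE(t₂), and t = 100 keeps the entire candidate
  region.
* **Unbiased edge placement at the default t = 95.** The level is then
  0.5: the half-maximum contour. For a step edge blurred by a symmetric
  PSF the half-maximum crosses the true edge position exactly, independent
  of the blur width, so bead recovery does not depend on knowing σ. A
  mapping that sends t = 95 to the level 0.05 instead (one natural reading
  of "keep the top 95%") would place the boundary ≈ 1.6 σ *outside* the
  true edge and inflate a 19.98 µm bead by over 1.5 µm; the calibration
  contract — recover the certified bead mode within one pixel — fixed the
  choice made here. The vendor's AdaptiveErode is proprietary; this
  construction is validated the same way the original workflow was, by
  bead recovery, not by algorithm identity.

The **loose default-style mask** is a filled 4-px dilation of the object
mask. Only the *ordering* loose > adaptive-erode of modal bead size is
meaningful (the 4.5–6 µm offsets reported for vendor defaults are
instrument-specific); 4 px guarantees a ≥ 2 µm offset at 0.5 µm/px.

### Size features

All features are measured on the adaptive-erode mask and reported in
micrometres; intensities are summed background-subtracted absorbances over
the object mask. Pixel-centre coordinates understate physical extent by one
pixel (a row of N pixels spans N px, but its centres span N − 1), so the
extent-like features carry a +1 px endpoint correction:

* **Area / Diameter.** Area = foreground count × px²;
  Diameter = 2·√(Area/π) exactly, so Diameter² · π / 4 ≡ Area to machine
  precision by construction.
* **Height / Width.** Sides of the minimum-area *rotated* bounding
  rectangle (rotating calipers over the hull of boundary-pixel centres,
  + 1 px per side). An axis-aligned box would make these features
  orientation-dependent. Axis-aligned rectangles measure exactly; rotated
  ones within 1 px. Using pixel-square corners instead would bias
  45°-rotated rectangles by ≈ +1.4 px.
* **Major Axis.** 4·√(largest eigenvalue) of the pixel covariance with the
  per-pixel 1/12 variance of a unit square added, the standard moments
  ellipse; a square of side s then measures s·√(4/3) exactly. Degenerate
  collinear masks fall back to the geodesic length.
* **Length.** The geodesic diameter: the longest shortest-path between
  boundary pixels *inside* the mask, + 1 px, so a folded grain is measured
  along its fold. Distances use a 16-neighbour graph (axial 1, diagonal √2,
  knight moves √5 with both intermediate cells required inside), and any
  endpoint pair whose straight segment stays inside the mask is upgraded to
  its exact Euclidean distance. Convex masks therefore yield the exact
  pixel-centre max Feret diameter, and the chamfer fallback for folded
  shapes overestimates by at most ≈ 2.8% (an 8-neighbour metric would err
  by up to 8.2%, which is why the larger neighbourhood is used). Masks up
  to 20 000 px are measured exactly over all boundary pairs (compiled
  code); larger masks use an iterated farthest-point sweep whose error on
  convex shapes stays below 2%.
* **Thickness Max.** 2 × the maximum of the Euclidean distance transform
  against background (frame padded). Measured centre-to-centre this already
  returns a rectangle's exact shorter side and a disk's diameter within
  1 px, so *no* additional +1 px is added here.
* **Circularity.** Mean over boundary pixels of the distance to the
  centroid divided by the SD of that distance, capped at 100 when the SD
  falls below 1% of the mean. Only its ordering is used (singles score
  high, doublets low). For near-perfect disks the SD is pure discretization
  noise, so the score grows with size until it caps — scale invariance
  holds only when the boundary-radius spread is shape-driven. Masks with
  fewer than 8 boundary pixels return `NA`.
* **Elongatedness.** Height/Width; ≈ 1 for polar views of oblate grains,
  ≈ the view aspect for equatorial views, which is what makes it the view
  sorter.

### Gating

Gates run in a fixed cascade and every object receives exactly one terminal
label, so counts are conserved: extraction failures → `debris`; Otsu
thresholds on log10(1 + intensity) per brightfield channel (below on both
channels → `debris`; with one camera, the single channel decides); border
touch → `cropped` (a hard instrument flag, applied before the data-driven
gates so half-moon silhouettes cannot distort the circularity density);
circularity below the deepest kernel-density valley → `multiple`; modified
z-scores (0.6745·(x − median)/MAD, cutoff 3.5) on log area and
elongatedness → `outlier`; the rest → `hq_single`. The manual
image-inspection step of instrument workflows is replaced by these
automated flags, which that workflow itself suggests as the automatable
substitute. Every data-driven threshold accepts a config override so a
manual gate can be replayed exactly.

A kernel-density valley is only believed when the flanking modes are
separated by more than a feature-scale minimum (0.15 in elongatedness,
2 in circularity) *and* the valley dips below half the smaller mode.
Without the separation floor, pixel quantization of near-spherical grains
(elongatedness values like 1.000/1.017/1.024) fabricates deep but
meaningless valleys. Unimodal distributions pass everything, with a
warning. With fewer than 8 records the outlier stage is skipped.

### Summaries

Species size is reported at two levels: pooled over all HQ pollen, and as
the mean of per-individual means with equal weight per plant. Uneven pollen
counts per plant would otherwise let one heavily sampled individual drag
the species mean; the individual-means level is the one meant for method
comparison. The modal size uses histogram bins of one pixel — the
resolution limit of the features — and ties resolve to the lowest bin.

## The synthetic generator

The generator's role is ground truth, not photorealism. It renders disks
(beads, spheroid pollen, polar views of oblate grains), ellipses
(equatorial oblate views, aspect 1.6), capsules (elongated grains, aspect
3), a corpus disk of diameter d with two 0.6 d sacci at ±0.55 d (saccate
Pinaceae-like grains, total span 1.7 d), overlapping disk pairs
(doublets), low-contrast multi-blob debris, and border-clipped disks
(cropped frames). Class counts are multinomial; sizes are Gaussian within
class (CV 8% by default, spanning ≈ 20–70 µm across classes, the range of
anemophilous pollen); individuals carry Gaussian mean offsets (SD 0.8 µm,
the order of reported between-tree differences in birch) and years optional
fixed shifts. Frames are 1.8 × the object's span, so only the cropped class
touches the border. Defaults: background 0.75, contrast 0.5 (debris 0.12),
blur σ = 1 px, noise SD 0.02 — i.e. 2% of full scale. Coverage is computed
by 4×4 supersampling, and the truth table stores the generating length and
the analytic (or finely rasterized, for unions) area.

What the generator does **not** emulate: surface texture and pori, optical
diffraction, fluorescence, shot noise, multiple grains per frame beyond
touching doublets, and a second physical camera (both intensity columns are
filled from the one rendered channel; the single-channel debris gate is the
code path such data exercises). Tests passing on these fixtures therefore
validate the geometry and statistics of the pipeline, not its robustness to
heavily sculptured or out-of-focus real imagery.

Brownian-motion traits are simulated edge-by-edge with increments
N(0, σ²·branch length) from root state 0, giving tip covariance equal to
σ² times the shared-branch-length matrix — the fixture for the Blomberg's K
machinery.

## Phylogenetic signal

K is computed exactly from its definition: with V the shared-branch-length
matrix and â the GLS phylogenetic mean, K is the observed MSE0/MSE over its
Brownian expectation (trace(V) − n/Σ(V⁻¹)) / (n − 1). Algebraic
consequences used as tests: K ≡ 1 on star phylogenies for *any* trait, K is
invariant to affine trait transforms, and K averages 1 over Brownian
replicates. Any input tree is interpreted as rooted at its root node — star
trees, which common rootedness checks reject, are deliberately valid input
here because the star identity is a core correctness check. The
randomization test shuffles tip values and uses the
(count + 1)/(n_perm + 1) estimator (never exactly zero; 1000 permutations
resolve p = 0.001), one-sided for K* ≥ K because the question is the
*presence* of signal. Species absent from a dated reference tree are
attached at their genus: at the genus MRCA when two or more congeners
exist (terminal length = mean congener depth below that node), at the
midpoint of the terminal branch for a single congener — both preserve
ultrametricity. The midpoint rule for monotypic attachment is a documented
convention; reference implementations vary here, so external K
reproductions can differ in later decimals. Tip renames are supplied as an
explicit map, never hard-coded.

## Agreement statistics

Bland–Altman differences are IFC − literature (negative bias ⇒ literature
larger), limit lines at the mean difference ±1 SD and ±2 SD — the
convention of the workflow this package reimplements, not the usual
±1.96 SD. When a literature source gives min/mean/max, the mean is the
comparator. `ols_fit()` optionally log10-transforms the predictor, the
model form used for IFC-versus-literature fits; adjusted
R² = 1 − (1 − r²)(n − 1)/(n − 2) with df = n − 2.

## Numerical choices and degenerate inputs

* Empty frames raise a typed `empty_object` condition; batch extraction
  converts it to a status row, never dropping objects.
* An empty adaptive-erode candidate set falls back to the object mask with
  a warning; degenerate constant images are flagged at background
  estimation (scale 0).
* Ties in the modal histogram go to the lowest bin; `which.max`
  makes this deterministic.
* Single-pixel masks measure one pixel in every extent feature; single-
  individual species report `NA` SD at the individual-means level; groups
  of one report `NA` SD in difference summaries.
* All randomness is seed-controlled: galleries are bit-identical under a
  repeated seed, and the permutation seed is recorded in the K result.

## Problem sizes

The shipped tests exercise: 1000 beads for the calibration mode (plus 120
through the loose mask for the ordering check), mixed galleries of 250
objects and oblate galleries of 120 for gating recall, 500 Brownian
replicates on a 50-tip tree for the K recovery check, and 400 null
randomization runs at 200 permutations for the test-size check — sizes
chosen so the whole suite completes in minutes on one CPU while keeping
Monte-Carlo error well inside the asserted bounds.

## Known limitations

Masking assumes one dominant object per frame; multi-object segmentation is
out of scope. The circularity score is not the vendor's undisclosed
formula, only order-compatible with it. The debris and view gates are
data-driven and need visible bimodality (or an explicit override). The
geodesic fallback for very large folded masks is a heuristic with a proven
bound only on convex shapes. Real brightfield texture can move the
half-maximum contour in ways the silhouette model cannot represent; the
bead contract calibrates the mask for smooth-edged particles.
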