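# ifcpollen

Pollen grain size is a classical palynological trait, but traditional light
microscopy measures at most a few dozen grains per sample. Imaging flow
cytometry (IFC) photographs thousands of individual particles per minute in
brightfield, turning pollen sizing into an image-analysis problem: segment
each grain, measure it in micrometres, throw away debris, doublets and
cropped frames, and aggregate honestly across individual plants. `ifcpollen`
is an open, tested R implementation of that workflow for people working on
pollen morphometry, aerobiology and trait evolution — including the
downstream statistics used to compare IFC sizes with published microscopy
values and to test for phylogenetic signal.

## What it computes

* **Synthetic galleries with ground truth** (`render_gallery()`,
  `render_bead()`, `simulate_bm_trait()`): brightfield-like images of
  calibration beads, spheroid/oblate/elongated/saccate pollen, debris,
  doublets and frame-cropped objects, each with an exact truth record, so
  every downstream stage is testable without instrument data.
* **Masks** (`object_mask()`, `adaptive_erode_mask()`,
  `default_loose_mask()`): an Otsu object mask on the contrast map
  |I − background|, and an adaptive-erode refinement that cuts the mask at a
  contrast level set by its threshold t (level = (100 − t)/10 of the robust
  contrast scale). At the default t = 95 the cut sits on the half-maximum
  contour, the unbiased edge locator under symmetric blur; a deliberately
  loose mask (fixed 4 px dilation) emulates vendor defaults that overestimate
  size.
* **Six size features in µm** (`extract_features()`): area-equivalent
  diameter D = 2·√(A/π); bounding-rectangle Height/Width (minimum-area
  rotated rectangle); best-fit-ellipse Major Axis (4·√λ̂max of the pixel
  covariance); fold-tolerant Length (geodesic diameter of the mask, computed
  in compiled code); Thickness Max (2 × max of the Euclidean distance
  transform); plus Circularity and Elongatedness for gating.
* **Gating** (`apply_gates()`, `sort_views()`): debris by Otsu thresholds on
  log brightfield intensities, doublets by the circularity density valley,
  cropped frames by border touch, oversized masks by median/MAD modified
  z-scores; oblate grains sorted into polar/equatorial views on the
  elongatedness histogram. Labels partition the input exactly.
* **Summaries and calibration** (`summarize_sizes()`, `modal_size()`):
  species mean ± SD both pooled over pollen and over per-individual means
  (equal weight per plant), and histogram modes at pixel resolution for
  bead-based calibration against the NIST-traceable L20 standard
  (certified modal diameter 19.98 µm).
* **Method agreement** (`bland_altman()`, `group_diff_summary()`,
  `pearson_r()`, `ols_fit()`): Bland–Altman mean difference ± SD of
  differences with ±1 SD/±2 SD limit lines (sign convention IFC − literature),
  per-family summaries, Pearson r, and OLS fits with adjusted R².
* **Phylogenetic signal** (`blombergs_k()`, `k_randomization_test()`,
  `add_tip_to_genus()`): Blomberg's K
  (K = (MSE0/MSE) / E[MSE0/MSE], phylogenetic mean
  â = (1ᵀV⁻¹1)⁻¹1ᵀV⁻¹x) with a one-sided permutation test
  p = (1 + #{K* ≥ K}) / (n + 1), plus Newick pruning, tip renaming and
  genus-level tip addition on dated trees.

## Worked example

```r
library(ifcpollen)

g <- render_gallery(150, c(spheroid = 0.6, debris = 0.2,
                           doublet = 0.1, cropped = 0.1),
                    seed = 7, n_individuals = 3,
                    species_label = "Betula_pendula")
res <- run_pipeline(run_config(seed = 7), g)
res$counts
#>   cropped    debris hq_single  multiple
#>        17        30        88        15
res$summaries
#>    species_label            level n_individuals n_pollen mean_um  sd_um
#> 1 Betula_pendula    pooled_pollen             3       88   25.62 1.8849
#> 2 Betula_pendula individual_means             3       88   25.56 0.5309
```

Every simulated object received exactly one terminal gate label (the counts
sum to 150). The 88 surviving HQ singles average 25.62 µm pooled and
25.56 µm when each of the three simulated plants contributes equally — the
level used for method comparison; the generator's true mean for those
objects is 25.19 µm, i.e. recovery within 2%. A command-line front end with
`simulate | extract | gate | summarize | agree | physig | run` subcommands
lives in `inst/cli/ifcpollen.R`.

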