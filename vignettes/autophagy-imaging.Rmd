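---
title: "Quantifying autophagy and viral reporter expression in macrophage micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying autophagy and viral reporter expression in macrophage micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(autophagr)
```

## The problem

Primary human macrophages differentiated with or without interleukin-27
differ dramatically in autophagosome content, and autophagosome-rich cells
exclude an HIV-1 fluorescent reporter. Quantifying either observation from
micrographs requires two related analyses:

1. **Single-cell analysis.** Cells carry no membrane stain, so their
   footprints must be segmented from the label-free transmitted-light (DIC)
   channel. Each cell's mean fluorescence intensity (MFI) in the
   autophagosome dye (Cyto-ID, green) and viral reporter (DsRed, red)
   channels is then read out, and the two-channel scatter is partitioned
   into quadrants by one positivity gate per channel.
2. **Field-level quantification.** Autophagy induction is summarized per
   field as the total dye-stained area divided by the number of cells
   (nuclei counted from the Hoechst channel), and conditions are compared
   by the fold change of group means with a two-tailed unpaired t-test.

`autophagr` implements both analyses as composable functions over plain
intensity matrices, together with a synthetic-scene generator that plants
ground truth, so every stage is testable without acquired images.

## The DIC segmentation operator chain

`segment_dic()` applies, in order: histogram equalization (0% saturation),
Sobel edge magnitude, a minimum rank filter (radius 0), a maximum rank
filter (radius 5), 3×3 mean smoothing, linear rescale to 8 bits,
rolling-ball background subtraction, automatic thresholding, a grayscale
close → dilate → erode sequence, watershed splitting of touching
particles, and connected-component labeling with a particle-size window.

Each operator is specified mathematically rather than borrowed from an
imaging toolbox, and each is pinned to a brute-force oracle in the test
suite (a scalar-loop reimplementation, exhaustive neighborhood scan,
flood fill, or exact brute-force distance computation):

* **Rank filters** take the min/max over a disk whose membership rule is
  `di² + dj² ≤ r²` (so radius 1 is the 5-pixel cross, and radius 0 is the
  identity — the minimum filter at radius 0 is kept literally, as a
  documented no-op, for fidelity to the published parameter list).
  Borders replicate edge pixels, here and in every other filter.
* **Histogram equalization** remaps intensity `v` to
  `max_range · F(v)` where `F` is the cumulative (by default
  square-rooted, the common interactive default) histogram; a constant
  image is returned unchanged.
* **Rolling-ball background subtraction** estimates the background as the
  grayscale opening by a large disk (default radius 50 px) and subtracts
  it, clipped at zero. A fixed-offset variant covers the
  manual-background-threshold reading of the protocol; opening is the
  default.
* **Thresholding** offers the isodata intermeans fixed point (default),
  Otsu's criterion (ties resolve to the mean of the maximizing plateau),
  and fixed values; masks use the strict `> T` rule.
* **The watershed** floods the negated exact Euclidean distance transform
  from its h-maxima (peak-merge tolerance `h = 1` distance unit by
  default, so maxima less prominent than 1 px of distance never seed a
  basin) and inserts single-pixel background lines where basins meet.
  The distance transform is the exact two-pass squared-distance
  algorithm, not a chamfer approximation.
* **Component labeling** numbers particles in raster-scan discovery order
  and applies an inclusive `[min_area, max_area]` window.

### Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `saturation` | 0 | fraction | published protocol value |
| `min_radius`, `max_radius` | 0, 5 | px | published protocol values |
| `morph_radius` | 3 | px | unstated in the protocol; a disk of radius 3 closes the residual gaps left by a radius-5 maximum filter without merging neighbors |
| `ball_radius` | 50 | px | the conventional rolling-ball default |
| `threshold_method` | isodata | — | the classic auto-threshold; configurable |
| `min_area` | 50 | px² | a generic debris floor; see below |
| `watershed_h` | 1 | distance units | smallest non-trivial prominence on an integer-valued distance map |

**Sizing the particle window to the magnification.** At ×10, a macrophage
footprint (radius ≈ 6–18 px here) plus the halo added by the radius-5
maximum filter yields ROIs of roughly 400 px² upward, while noise-driven
debris stays below ≈ 150 px². The packaged field analyses and the
acceptance checks therefore run with `min_area = 200` px²; the generic
default of 50 px² is kept on `segmentation_params()` itself for
protocol fidelity, but an operator should always match the window to the
expected cell size, exactly as one would in the interactive tool.

MFIs are always measured on the raw fluorescence channels: display
enhancement (equalization) is part of segmentation only, and measurement
must not follow it.

## Gating

The published scatter analysis shows quadrants but no gating rule, so
`derive_gate_threshold()` is explicit about the convention: a fixed value,
a nearest-rank percentile, or mean + k·sd of a designated negative-control
population (default, k = 3). Positivity is strict (`MFI > gate`), counts
always sum to the number of cells.

A k-sigma gate admits its Gaussian tail by construction — about 0.13% of
true negatives at k = 3, and more when the control is small (a 20-cell
control estimates the sd within ~±16%, so an intended 3σ cut can act as a
2σ one). The populations this pipeline separates sit tens of sigma apart
(basal green MFI ≈ 1 a.u. vs induced ≈ 15; red background ≈ 8 ± 0.2 vs
reporter-positive ≈ 100), so the demonstration of red/green mutual
exclusivity in the acceptance checks uses k = 5, the usual choice when a
sub-1% false-positive rate is the target. The package default stays k = 3.

## Field-level quantification

`measure_stained_area()` thresholds the dye channel with a `"halfmax"`
background threshold by default: midway between the background level (the
median — stained pixels are sparse) and the brightest stain (the maximum),
floored at five robust standard deviations (MAD) above background so that
a stain-free noisy field measures ≈ 0. The channel is thresholded **raw**:
autophagosome puncta approach the pixel scale, and pre-smoothing dilutes
one-to-nine-pixel puncta below any unbiased threshold while spreading
halos around larger ones (an optional 3×3 pre-smooth remains available
for noise regimes that demand it). A half-amplitude threshold crosses each
punctum boundary symmetrically, so the pixel count is an unbiased area
estimate whenever noise is small relative to the stain amplitude.

`count_cells_from_nuclei()` smooths the nuclear channel (nuclei are large
blobs, so smoothing only helps), thresholds, watershed-splits touching
nuclei and counts particles within a 30–1000 px² window — sized for
nuclei at ×10. `quantify_field()` divides stained area by cell count and
flags zero-cell fields as undefined (`NA`, excluded downstream with a
warning).

`compare_conditions()` reports the fold change of group means (ratio of
means, not mean of ratios — matching an "average stained area per cell
per condition" readout) and the two-tailed unpaired t-test, pooled
(Student) by default with a Welch flag. The statistic is implemented in
closed form so the degenerate zero-variance-equal-means case can return
`t = 0, p = 1` exactly; the test suite pins both variants to
`stats::t.test` at 10⁻⁹ on a thousand random group pairs. The replicate
unit is one field/experiment value, mirroring an n = 5
independent-experiment design.

## The synthetic scene generator

`generate_scene()` renders what the analysis assumes and nothing more:

* **DIC**: each cell is a disk with a directional intensity ramp (relief
  shading, amplitude 40 a.u. over a 120 a.u. background) plus
  intracellular Gaussian texture (sd 25 a.u.). The texture is part of the
  cell rendering, not the noise model: real DIC macrophages are strongly
  granular, and it is the granularity that gives the edge detector
  contrast on the two flanks perpendicular to the shear direction, where
  relief shading vanishes.
* **Blue**: Gaussian nucleus blobs (radius ≈ 0.35 × cell radius, floored
  at 3.5 px — nuclei vary far less than cell footprints).
* **Green**: perinuclear puncta (disks of radius 1.5–2 px, topped up by
  pixel accretion onto existing puncta) whose union area matches the
  planted per-cell target to within a couple of pixels. Per-cell targets
  follow a truncated normal law of the cell-area fraction
  (mean 0.005, sd 0.002, truncated to [10⁻⁴, 0.02]) scaled by the
  condition multiplier: ×1 (basal), ×20 (induced), ×10 (lysosomal
  block on basal), ×60 (block on induced). Because the multiplier scales
  identical base draws, two scenes from one seed have planted totals in
  exactly the ratio of their multipliers.
* **Red**: a whole-cell fill for the reporter-positive subpopulation.
  With `mutual_exclusive = TRUE`, reporter-positive cells are forced to
  basal green and green-high cells carry no red — the structure the
  single-cell analysis is designed to reveal.
* Background, an optional illumination ramp, Gaussian noise and optional
  Poisson resampling are applied last. All randomness comes from one
  seeded stream in a documented order, so scenes are bit-reproducible.

**Signal-to-noise convention.** The scene has one noise amplitude; SNR is
defined against the weakest signal the method depends on, the DIC relief
amplitude: SNR 5 means `noise_sd = 40 / 5 = 8` a.u. on every channel.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: optics (no point-spread function, no defocus),
cell-shape heterogeneity beyond disks, spatially correlated backgrounds,
staining variability between cells of one class, cross-channel bleed, and
cells touching in clumps larger than pairs. Results on synthetic scenes
bound the pipeline's correctness, not its performance on any particular
microscope.

## Composite images and reproducibility

Motorized-stage composites (2×3 for the single-cell analysis, 2×2 for the
quantification) are cut into exact tiles with recorded 0-based offsets
(`split_composite()`); tiles are analyzed independently and ROI
coordinates mapped back to the composite frame. No seam rule is invented:
cells cut by a seam are counted per tile, a deliberate, documented bias.

`run_pipeline()` executes either analysis (optionally preceded by
simulation), writes CSV artifacts, and echoes every parameter actually
used to `run_log.yaml`; identical configuration and seed give
byte-identical outputs. Configurations round-trip losslessly through YAML
(`run_config()` / `write_run_config()` / `read_run_config()`), and
unknown keys are rejected by name.

## Problem sizes used by the tests and acceptance script

The validation suite uses fields of 256–384 px square with 20–25 cells,
5 replicate fields per condition for fold-recovery checks (planted folds
2–20), 100 random ≤ 32×32 images per operator-oracle comparison, and
1000 random group pairs for the t-statistic cross-check. These sizes give
stable estimates of every quantity checked while keeping a full run in
the minutes range; all are parameters, not limits.

## Known limitations

* Pure-R implementations of the rank filters and watershed favor clarity;
  they are exact but slower than compiled imaging libraries on large
  mosaics (a 384×384 field segments in a few seconds).
* The watershed's ordered-descent flooding defers pixels reached before
  any labeled neighbor; on pathological masks (e.g. spirals) basin
  boundaries can shift by a pixel relative to a priority-queue flooding.
* Stained-area measurement assumes stain amplitude well above noise; at
  amplitude-to-noise ratios near 1 no unbiased threshold exists at the
  pixel scale.
* The fold change of means is reported without a confidence interval; the
  t-test addresses the difference of means, not the ratio.
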