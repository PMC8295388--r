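# autophagr

Image-based quantification of autophagy induction and HIV reporter
expression in primary macrophage micrographs — as a tested, reusable R
pipeline.

Macrophages differentiated in the presence of interleukin-27 accumulate
autophagosomes (visualized with the Cyto-ID dye, green) and exclude a
DsRed HIV-1 reporter (red). Quantifying those observations requires
analyses that microscopy studies usually run interactively, step by step,
in an image-processing GUI; `autophagr` re-implements the whole chain as
documented, tested functions:

* **Label-free single-cell segmentation** from the DIC (transmitted light)
  channel: histogram equalization → Sobel edge magnitude → minimum
  (radius 0) and maximum (radius 5) rank filters → 3×3 smoothing → 8-bit
  conversion → rolling-ball background subtraction → auto-threshold →
  grayscale close/dilate/erode → distance-transform watershed →
  particle analysis. Every operator (`rank_filter()`, `sobel_edges()`,
  `binary_watershed()`, `label_components()`, …) is exposed on its own
  and pinned to a brute-force oracle in the test suite.
* **Per-cell readout and quadrant gating**: `extract_roi_means()` returns
  a tibble of per-ROI areas, centroids and mean fluorescence intensities
  (MFI); `gate_quadrants()` partitions the green × red scatter by one
  positivity gate per channel (gates from a negative-control population
  via `derive_gate_threshold()`).
* **Autophagy quantification per field**: total stained area
  (`measure_stained_area()`) over the nucleus count
  (`count_cells_from_nuclei()`), compared between conditions as the fold
  change of group means with a two-tailed unpaired t-test
  (`compare_conditions()`): for conditions *a*, *b* with per-field values
  of stained area per cell,

  fold = mean(b) / mean(a),  t = (mean(b) − mean(a)) / (s_p √(1/n_a + 1/n_b)),

  with the pooled standard deviation s_p (Welch variant by flag).
* **A synthetic micrograph generator** (`generate_scene()`) that renders
  DIC/blue/green/red fields of relief-shaded, textured cells with planted
  ground truth — per-cell green-area targets scaled ×1/×20/×10/×60 by
  condition presets, a red-positive subpopulation, and enforced
  red/green mutual exclusivity — so the entire pipeline is verifiable
  without any acquired image.
* Small helpers for expression screens and immunoblots:
  `filter_differential()` (strict |fold| and p cutoffs by direction),
  `band_ratio()` and `lc3_lipidation()`.

Results come back as tibbles or as small S3 objects with `tidy()`,
`glance()` and `autoplot()` methods, so everything composes with the
tidyverse. See the vignette (`vignettes/autophagy-imaging.Rmd`) for the
model, parameter choices and limitations.

## Worked example

Simulate an induced field, segment it from DIC, and score the detections
against the planted truth:

```r
library(autophagr)

sc   <- generate_scene(scene_params(n_cells = 22, seed = 11, noise_sd = 8))
labs <- segment_dic(sc$channels$DIC, segmentation_params(min_area = 200))
rois <- extract_roi_means(labs, list(green = sc$channels$green,
                                     red   = sc$channels$red))
match_detections_to_truth(rois, sc$truth, match_radius = 12)
#> # A tibble: 1 × 6
#>   n_truth n_detected n_matched precision recall    f1
#>     <int>      <int>     <int>     <dbl>  <dbl> <dbl>
#> 1      22         25        22      0.88      1 0.936
```

All 22 planted cells are recovered (recall 1) with three spurious small
ROIs at this noise level (SNR 5), for a detection F1 of 0.94.

Quantify autophagy between a basal and an induced condition, five
replicate fields each:

```r
area_per_cell <- function(cond, offset) {
  sapply(1:5, function(i) {
    s <- generate_scene(scene_params(height = 256, width = 256,
      n_cells = 20, min_distance = 30, condition = cond,
      noise_sd = 8, seed = offset + i))
    quantify_field(s$channels$green, s$channels$blue)$area_per_cell
  })
}
compare_conditions(area_per_cell("AB", 40), area_per_cell("ABI", 50),
                   labels = c("AB", "ABI"))
#> <condition_comparison> AB (n=5, mean 2.39) vs ABI (n=5, mean 43.11)
#>   fold change (ABI/AB): 18.04;  student t = 54.43, df = 8, two-tailed p = 1.44e-11
```

The planted 20-fold difference in stained area per cell is recovered as
18.0× and is overwhelmingly significant at n = 5 fields per condition.

A thin command-line wrapper over the same functions is installed as
`exec/autophagr` (subcommands `simulate`, `segment-dic`, `gate`,
`quantify-autophagy`, `compare`, `filter-diff`, `run`).

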