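Package: autophagr
Title: Label-Free Single-Cell Quantification of Autophagy and Viral
    Reporter Expression in Macrophage Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify autophagy induction and HIV reporter
    expression in fluorescence micrographs of adherent macrophages.
    Implements a label-free segmentation pipeline that outlines cells from
    the differential interference contrast (DIC) channel using histogram
    equalization, Sobel edge detection, rank filtering, rolling-ball
    background subtraction, grayscale morphology and distance-transform
    watershed splitting; extracts per-cell mean fluorescence intensities
    and performs two-channel quadrant gating; measures the
    autophagosome-stained area per cell from dye and nuclear counterstain
    channels and tests between-condition fold changes with unpaired
    t-tests; and simulates multi-channel macrophage fields with planted
    ground truth so every stage can be validated without acquired images.
    Also includes small helpers for differential-expression filtering and
    immunoblot densitometry ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    png,
    stats,
    tibble,
    tiff,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
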