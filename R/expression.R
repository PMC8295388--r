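#' Filter a differential-expression table by fold change and p-value
#'
#' Applies the standard microarray screening rule to an already-normalized
#' expression table: keep genes with `|fold_change| > fold_cutoff`
#' (strictly, i.e. "more than n-fold") in the requested direction and
#' `p_value < p_cutoff` (strictly). Fold changes use the signed microarray
#' convention: `b/a` when the ratio is >= 1, else `-a/b`, so values never
#' fall in (-1, 1); a `fold_change` column is recomputed from `mean_a` /
#' `mean_b` when absent. The filter is monotone: raising `fold_cutoff` or
#' lowering `p_cutoff` never adds genes.
#'
#' @param records Data frame with columns `gene_id`, `p_value`, and either
#'   `fold_change` (signed convention) or `mean_a` and `mean_b` (positive
#'   normalized expressions).
#' @param fold_cutoff Positive fold-change cutoff (e.g. 3).
#' @param p_cutoff Positive p-value cutoff (e.g. 0.05).
#' @param direction `"up"` (fold > 0), `"down"` (fold < 0) or `"both"`.
#' @return The surviving rows, as a tibble, with a `fold_change` column.
#' @export
#'
#' @examples
#' tbl <- tibble::tibble(
#'   gene_id = c("geneX", "geneY", "geneZ"),
#'   fold_change = c(3.5, 2, -3.2),
#'   p_value = c(0.01, 0.01, 0.04)
#' )
#' filter_differential(tbl, 3, 0.05, "up")$gene_id # geneX
#' filter_differential(tbl, 3, 0.05, "down")$gene_id # geneZ
filter_differential <- function(records, fold_cutoff = 3, p_cutoff = 0.05,
                                direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (fold_cutoff <= 0 || p_cutoff <= 0) {
    stop("cutoffs must be > 0", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  if (!"fold_change" %in% names(records)) {
    if (!all(c("mean_a", "mean_b") %in% names(records))) {
      stop("`records` needs a `fold_change` column or `mean_a`/`mean_b`",
        call. = FALSE
      )
    }
    if (nrow(records) && any(records$mean_a <= 0 | records$mean_b <= 0)) {
      stop("expressions must be > 0", call. = FALSE)
    }
    ratio <- records$mean_b / records$mean_a
    records$fold_change <- ifelse(ratio >= 1, ratio, -1 / ratio)
  }
  if (!"p_value" %in% names(records)) {
    stop("`records` needs a `p_value` column", call. = FALSE)
  }
  keep <- abs(records$fold_change) > fold_cutoff &
    records$p_value < p_cutoff
  keep <- keep & switch(direction,
    up = records$fold_change > 0,
    down = records$fold_change < 0,
    both = TRUE
  )
  records[which(keep), , drop = FALSE]
}

#' Immunoblot densitometry ratios
#'
#' `band_ratio()` is the plain ratio of two band intensities (e.g.
#' phosphorylated over total protein). `lc3_lipidation()` is the lipidated
#' fraction of the autophagosome marker LC3: `LC3-II / (LC3-I + LC3-II)`,
#' bounded in `[0, 1]`. Band intensities are assumed already measured by
#' lane profiling; extraction from blot images is out of scope.
#'
#' @param numerator,denominator Band intensities (a.u.); the denominator
#'   must be > 0.
#' @return A single ratio.
#' @export
#'
#' @examples
#' band_ratio(3, 9) # 1/3
#' lc3_lipidation(3, 9) # 0.75
band_ratio <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("denominator intensity must be > 0", call. = FALSE)
  }
  numerator / denominator
}

#' @rdname band_ratio
#' @param lc3_i,lc3_ii Intensities of the cytosolic (LC3-I) and lipidated
#'   (LC3-II) bands; their sum must be > 0.
#' @export
lc3_lipidation <- function(lc3_i, lc3_ii) {
  if (any(lc3_i < 0) || any(lc3_ii < 0)) {
    stop("band intensities must be >= 0", call. = FALSE)
  }
  band_ratio(lc3_ii, lc3_i + lc3_ii)
}
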