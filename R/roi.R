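#' Per-ROI areas, centroids and mean fluorescence intensities
#'
#' For every labeled cell ROI, computes its area (px^2), centroid (0-based
#' row/col, px) and the arithmetic mean intensity of each supplied
#' fluorescence channel over the ROI's pixels. Measurement is intended to
#' run on the raw fluorescence channels, not on display-enhanced copies.
#'
#' @param labels A `labeled_mask` from [segment_dic()] or
#'   [label_components()].
#' @param channels Named list of numeric matrices congruent with `labels`
#'   (e.g. `list(green = ..., red = ...)`).
#' @return A tibble with one row per ROI: `roi_id`, `area`,
#'   `centroid_row`, `centroid_col`, and one `mfi_<channel>` column per
#'   channel.
#' @export
extract_roi_means <- function(labels, channels = list()) {
  check_image(labels)
  if (length(channels) && is.null(names(channels))) {
    stop("`channels` must be a named list", call. = FALSE)
  }
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), dim(labels))) {
      stop("channel `", nm, "` does not match the label mask shape",
        call. = FALSE
      )
    }
  }
  n <- max(labels, 0L)
  if (n == 0L) {
    out <- tibble::tibble(
      roi_id = integer(0), area = numeric(0),
      centroid_row = numeric(0), centroid_col = numeric(0)
    )
    for (nm in names(channels)) out[[paste0("mfi_", nm)]] <- numeric(0)
    return(out)
  }
  idx <- which(labels > 0L)
  lab <- as.integer(labels[idx])
  h <- nrow(labels)
  rows0 <- (idx - 1L) %% h # 0-based
  cols0 <- (idx - 1L) %/% h
  area <- tabulate(lab, nbins = n)
  out <- tibble::tibble(
    roi_id = seq_len(n),
    area = as.numeric(area),
    centroid_row = as.vector(rowsum(rows0, lab)) / area,
    centroid_col = as.vector(rowsum(cols0, lab)) / area
  )
  for (nm in names(channels)) {
    v <- as_pixel_matrix(channels[[nm]])[idx]
    out[[paste0("mfi_", nm)]] <- as.vector(rowsum(v, lab)) / area
  }
  out
}

#' Derive a positivity gate from a reference intensity population
#'
#' The published scatter analysis shows quadrants but states no gating
#' rule, so the gate is configurable: a fixed value, mean plus `k` sample
#' standard deviations (n - 1 denominator) of a designated
#' negative-control population — the default convention, with `k = 3` —
#' or a nearest-rank percentile.
#'
#' @param values Numeric vector of reference intensities (>= 2 values for
#'   the statistical methods).
#' @param method `"fixed"`, `"mean_plus_k_sd"` or `"percentile"`.
#' @param k_or_p The fixed value, the multiplier `k`, or the percentile
#'   `p` in `[0, 100]`, respectively.
#' @return The gate threshold (a single number).
#' @export
#'
#' @examples
#' derive_gate_threshold(c(1, 2, 3, 4), "mean_plus_k_sd", 3)
#' derive_gate_threshold(1:100, "percentile", 95)
derive_gate_threshold <- function(values,
                                  method = c("mean_plus_k_sd", "percentile", "fixed"),
                                  k_or_p = 3) {
  method <- match.arg(method)
  if (method == "fixed") {
    return(k_or_p)
  }
  if (length(values) < 2L) {
    stop("statistical gate methods need >= 2 reference values", call. = FALSE)
  }
  switch(method,
    mean_plus_k_sd = mean(values) + k_or_p * stats::sd(values),
    percentile = {
      if (k_or_p < 0 || k_or_p > 100) {
        stop("percentile must be in [0, 100]", call. = FALSE)
      }
      s <- sort(values)
      s[max(1L, ceiling(k_or_p / 100 * length(s)))]
    }
  )
}

#' Quadrant gating of a two-channel single-cell scatter
#'
#' Partitions per-cell mean fluorescence intensities (autophagosome dye on
#' the green axis, viral reporter on the red axis) into the four quadrants
#' defined by one threshold per channel. Positivity is strict
#' (`mfi > threshold`). Counts always sum to the number of cells and
#' fractions to 1.
#'
#' @param rois Tibble from [extract_roi_means()] (or any data frame with
#'   the two MFI columns).
#' @param green_threshold,red_threshold Gate thresholds (a.u.).
#' @param green_col,red_col Names of the MFI columns.
#' @return An object of class `quadrant_gating`: thresholds, per-quadrant
#'   `summary` (quadrant, count, fraction), the per-cell scatter table
#'   `cells` (with a `quadrant` column), and `n_cells`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
gate_quadrants <- function(rois, green_threshold, red_threshold,
                           green_col = "mfi_green", red_col = "mfi_red") {
  if (!all(c(green_col, red_col) %in% names(rois))) {
    stop("`rois` must contain columns `", green_col, "` and `", red_col, "`",
      call. = FALSE
    )
  }
  g <- rois[[green_col]]
  r <- rois[[red_col]]
  quadrants <- c("G-R-", "G+R-", "G-R+", "G+R+")
  q <- quadrants[1L + (g > green_threshold) + 2L * (r > red_threshold)]
  counts <- vapply(quadrants, function(x) sum(q == x), integer(1))
  n <- length(q)
  cells <- tibble::as_tibble(rois)
  cells$quadrant <- factor(q, levels = quadrants)
  structure(
    list(
      green_threshold = green_threshold,
      red_threshold = red_threshold,
      n_cells = n,
      summary = tibble::tibble(
        quadrant = factor(quadrants, levels = quadrants),
        count = as.integer(counts),
        fraction = if (n > 0) as.numeric(counts) / n else rep(NA_real_, 4)
      ),
      cells = cells,
      green_col = green_col, red_col = red_col
    ),
    class = "quadrant_gating"
  )
}

#' @export
print.quadrant_gating <- function(x, ...) {
  cat(sprintf(
    "<quadrant_gating> %d cells; gates: green > %.4g, red > %.4g\n",
    x$n_cells, x$green_threshold, x$red_threshold
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname gate_quadrants
#' @param x A `quadrant_gating` object.
#' @param ... Unused.
#' @method tidy quadrant_gating
#' @export
tidy.quadrant_gating <- function(x, ...) x$summary

#' @rdname gate_quadrants
#' @method glance quadrant_gating
#' @export
glance.quadrant_gating <- function(x, ...) {
  fr <- as.list(x$summary$fraction)
  names(fr) <- paste0(
    "fraction_",
    gsub("\\+", "pos_", gsub("-", "neg_", x$summary$quadrant))
  )
  names(fr) <- sub("_$", "", names(fr))
  tibble::as_tibble(c(
    list(
      n_cells = x$n_cells,
      green_threshold = x$green_threshold,
      red_threshold = x$red_threshold
    ),
    fr
  ))
}

#' @rdname gate_quadrants
#' @param object A `quadrant_gating` object.
#' @method autoplot quadrant_gating
#' @export
autoplot.quadrant_gating <- function(object, ...) {
  ggplot2::ggplot(
    object$cells,
    ggplot2::aes(
      x = .data[[object$green_col]], y = .data[[object$red_col]],
      colour = .data$quadrant
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$green_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$red_threshold, linetype = 2) +
    ggplot2::labs(
      x = "Autophagosome dye MFI (a.u.)",
      y = "Viral reporter MFI (a.u.)",
      colour = "Quadrant"
    ) +
    ggplot2::theme_minimal()
}
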