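#' Total stained area of a fluorescence channel
#'
#' Thresholds the autophagosome-dye channel against its background and
#' returns the number of mask-positive pixels (px^2). The default
#' `"halfmax"` method emulates a manually chosen background threshold: it
#' sits midway between the background level (the median, since stained
#' pixels are sparse) and the brightest stain (the maximum), floored at
#' five robust standard deviations above background. An all-background
#' channel then yields area 0. Puncta approach the pixel scale, so the
#' channel is thresholded raw by default; `smooth = TRUE` adds a 3x3 mean
#' first (useful when noise rivals the stain amplitude, at the cost of
#' diluting single-pixel structures). The isodata and
#' Otsu histogram methods and a fixed value are also available; the
#' histogram methods assume a substantial foreground fraction and error on
#' constant images.
#'
#' @param green Numeric matrix or `image_plane` (autophagosome channel).
#' @param threshold_method `"halfmax"`, `"isodata"`, `"otsu"` or
#'   `"fixed"`.
#' @param fixed_value Threshold when `threshold_method = "fixed"`.
#' @param smooth Apply the 3x3 mean before thresholding (default FALSE)?
#' @return Stained area in px^2, with the threshold used in attribute
#'   `"threshold"`.
#' @export
measure_stained_area <- function(green,
                                 threshold_method = c("halfmax", "isodata", "otsu", "fixed"),
                                 fixed_value = NULL, smooth = FALSE) {
  threshold_method <- match.arg(threshold_method)
  check_image(green)
  img <- if (smooth && threshold_method != "fixed") smooth_mean3(green) else green
  if (threshold_method == "halfmax") {
    m <- as_pixel_matrix(img)
    bg <- stats::median(m)
    sigma <- stats::mad(m)
    # midway between background and the brightest stain, floored at
    # 5 sigma above background so a stain-free noisy field measures ~0
    thr <- max((bg + max(m)) / 2, bg + 5 * sigma)
    mask <- binary_mask((m > thr) + 0L)
    attr(mask, "threshold") <- thr
  } else {
    mask <- auto_threshold(img, threshold_method, fixed_value = fixed_value)
  }
  out <- sum(mask == 1)
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Count cells from the nuclear counterstain channel
#'
#' Thresholds the nucleus channel, splits touching nuclei by watershed, and
#' counts particles within a nucleus-sized area window. The particle count
#' is the per-field cell number used as the denominator of the stained
#' area per cell.
#'
#' @param blue Numeric matrix or `image_plane` (nuclear channel).
#' @param threshold_method As in [measure_stained_area()].
#' @param fixed_value Threshold when `threshold_method = "fixed"`.
#' @param min_area,max_area Nucleus area window in px^2 (defaults 30 and
#'   1000, sized for x10 magnification).
#' @param watershed Split touching nuclei (default TRUE)?
#' @param watershed_h Peak-merge tolerance of the watershed.
#' @return Integer particle count, with the label mask in attribute
#'   `"labels"`.
#' @export
count_cells_from_nuclei <- function(blue,
                                    threshold_method = c("halfmax", "isodata", "otsu", "fixed"),
                                    fixed_value = NULL,
                                    min_area = 30, max_area = 1000,
                                    watershed = TRUE, watershed_h = 1) {
  threshold_method <- match.arg(threshold_method)
  check_image(blue)
  img <- smooth_mean3(blue)
  if (threshold_method == "halfmax") {
    m <- as_pixel_matrix(img)
    bg <- stats::median(m)
    thr <- max(
      (bg + stats::quantile(m, 0.999, names = FALSE)) / 2,
      bg + 5 * stats::mad(m)
    )
    mask <- binary_mask((m > thr) + 0L)
  } else {
    mask <- auto_threshold(img, threshold_method, fixed_value = fixed_value)
  }
  if (isTRUE(watershed)) {
    mask <- binary_watershed(mask, h = watershed_h)
  }
  labs <- label_components(mask, min_area = min_area, max_area = max_area)
  out <- n_components(labs)
  attr(out, "labels") <- labs
  out
}

#' Average stained area per cell for one field
#'
#' Combines [measure_stained_area()] on the dye channel with
#' [count_cells_from_nuclei()] on the counterstain channel of the same
#' field into the per-field summary statistic: total stained area divided
#' by cell count. A field with zero cells has an undefined ratio; it is
#' flagged with `NA` and a warning so downstream averaging can exclude it.
#'
#' @param green,blue Congruent numeric matrices (dye and nuclear channel).
#' @param field_id Identifier recorded in the output.
#' @param condition Condition label recorded in the output.
#' @param ... Passed on to both [measure_stained_area()] (thresholding
#'   arguments) and [count_cells_from_nuclei()] where they apply.
#' @return A one-row tibble: `field_id`, `condition`, `stained_area`,
#'   `cell_count`, `area_per_cell`.
#' @export
quantify_field <- function(green, blue, field_id = 1L, condition = NA_character_,
                           ...) {
  if (!identical(dim(green), dim(blue))) {
    stop("`green` and `blue` must have identical shape", call. = FALSE)
  }
  dots <- list(...)
  sa_args <- dots[names(dots) %in% names(formals(measure_stained_area))]
  cc_args <- dots[names(dots) %in% names(formals(count_cells_from_nuclei))]
  stained <- as.numeric(do.call(measure_stained_area, c(list(green), sa_args)))
  cells <- as.integer(do.call(count_cells_from_nuclei, c(list(blue), cc_args)))
  apc <- if (cells > 0) stained / cells else NA_real_
  if (cells == 0) {
    warning("field ", field_id, " has zero cells; area per cell undefined",
      call. = FALSE
    )
  }
  tibble::tibble(
    field_id = field_id, condition = condition,
    stained_area = stained, cell_count = cells,
    area_per_cell = apc
  )
}

#' Compare the stained area per cell between two conditions
#'
#' Fold change of group means (`b` over `a`) and a two-tailed unpaired
#' t-test between per-replicate area-per-cell values. The default is the
#' Student pooled-variance form; `var_equal = FALSE` switches to the
#' Welch-Satterthwaite variant. The degenerate case of zero variance in
#' both groups with equal means yields `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors of per-replicate values (each length >= 2);
#'   `NA`s (fields with undefined ratios) are dropped.
#' @param var_equal Pool the variances (Student, default) or not (Welch)?
#' @param labels Length-2 character vector naming the conditions.
#' @return An object of class `condition_comparison` with group summaries,
#'   `fold_change`, `t_statistic`, `df` and two-tailed `p_value`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
#'
#' @examples
#' compare_conditions(c(1, 2, 3), c(2, 4, 6))
compare_conditions <- function(a, b, var_equal = TRUE,
                               labels = c("a", "b")) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs >= 2 non-missing replicates", call. = FALSE)
  }
  na <- length(a)
  nb <- length(b)
  ma <- mean(a)
  mb <- mean(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    t_stat <- if (mb == ma) 0 else sign(mb - ma) * Inf
    df <- na + nb - 2 # Welch df is 0/0 here; report the pooled df
  } else {
    t_stat <- (mb - ma) / se
  }
  p <- if (is.finite(t_stat)) 2 * stats::pt(-abs(t_stat), df) else 0
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(
    list(
      labels = labels,
      n_a = na, n_b = nb, mean_a = ma, mean_b = mb,
      sd_a = sqrt(va), sd_b = sqrt(vb),
      fold_change = if (ma != 0) mb / ma else NA_real_,
      t_statistic = t_stat, df = df, p_value = p,
      method = if (var_equal) "student" else "welch"
    ),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<condition_comparison> %s (n=%d, mean %.4g) vs %s (n=%d, mean %.4g)\n",
      "  fold change (%s/%s): %.4g;  %s t = %.4g, df = %.4g, two-tailed p = %.4g\n"
    ),
    x$labels[1], x$n_a, x$mean_a, x$labels[2], x$n_b, x$mean_b,
    x$labels[2], x$labels[1], x$fold_change, x$method, x$t_statistic,
    x$df, x$p_value
  ))
  invisible(x)
}

#' @rdname compare_conditions
#' @param x,object A `condition_comparison`.
#' @param ... Unused.
#' @method tidy condition_comparison
#' @export
tidy.condition_comparison <- function(x, ...) {
  tibble::tibble(
    condition_a = x$labels[1], condition_b = x$labels[2],
    n_a = x$n_a, n_b = x$n_b,
    mean_a = x$mean_a, mean_b = x$mean_b,
    sd_a = x$sd_a, sd_b = x$sd_b,
    fold_change = x$fold_change,
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    method = x$method
  )
}

#' @rdname compare_conditions
#' @method glance condition_comparison
#' @export
glance.condition_comparison <- function(x, ...) {
  tibble::tibble(
    fold_change = x$fold_change, t_statistic = x$t_statistic,
    df = x$df, p_value = x$p_value, method = x$method
  )
}

#' @rdname compare_conditions
#' @method autoplot condition_comparison
#' @export
autoplot.condition_comparison <- function(object, ...) {
  d <- tibble::tibble(
    condition = factor(object$labels, levels = object$labels),
    mean = c(object$mean_a, object$mean_b),
    sd = c(object$sd_a, object$sd_b)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(width = 0.6, fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.15
    ) +
    ggplot2::labs(
      x = NULL, y = "Stained area per cell (px²/cell)",
      subtitle = sprintf(
        "fold change %.3g, two-tailed p = %.3g",
        object$fold_change, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}
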