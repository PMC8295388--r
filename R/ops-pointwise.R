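#' Convert an RGB triple to grayscale luminance
#'
#' Standard luminance weights: `0.299 R + 0.587 G + 0.114 B` per pixel. Used
#' as the first step when a transmitted-light channel was acquired in RGB
#' mode.
#'
#' @param r,g,b Numeric matrices of identical shape (the three channels), or
#'   a single list of three such matrices passed as `r`.
#' @return An `image_plane` (channel `"gray"`) of the same shape.
#' @export
#'
#' @examples
#' m <- matrix(100, 4, 4)
#' rgb_to_gray(m, m, m)[1, 1] # 100
rgb_to_gray <- function(r, g = NULL, b = NULL) {
  if (is.list(r) && is.null(g)) {
    b <- r[[3]]
    g <- r[[2]]
    r <- r[[1]]
  }
  check_image(r)
  check_image(g)
  check_image(b)
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b))) {
    stop("R, G and B planes must have identical shape", call. = FALSE)
  }
  out <- 0.299 * as_pixel_matrix(r) + 0.587 * as_pixel_matrix(g) +
    0.114 * as_pixel_matrix(b)
  restamp(out, r, channel = "gray")
}

#' Rescale an image linearly to 8-bit
#'
#' Maps the actual `[min, max]` intensity range onto `[0, 255]` and rounds
#' half-up. A constant image has no range and maps to 0.
#'
#' @param img Numeric matrix or `image_plane`.
#' @return An 8-bit `image_plane` of integers in `[0, 255]`.
#' @export
to_8bit <- function(img) {
  check_image(img)
  m <- as_pixel_matrix(img)
  lo <- min(m)
  hi <- max(m)
  out <- if (hi > lo) floor((m - lo) / (hi - lo) * 255 + 0.5) else m * 0
  restamp(out, img, bit_depth = 8)
}

#' Histogram equalization
#'
#' Monotone intensity remap by the cumulative histogram, the contrast
#' enhancement applied to the DIC channel before edge detection. Intensities
#' are binned to the integer levels of the image's bit depth; each level `v`
#' maps to `max_range * F(v)` where `F` is the cumulative distribution of
#' the (optionally square-rooted) histogram counts. With `sqrt_variant =
#' TRUE` (the default, matching the common interactive implementation) the
#' counts are square-rooted before cumulation, which softens the influence
#' of dominant background levels; `sqrt_variant = FALSE` is classical
#' equalization, whose output histogram is approximately uniform. A
#' saturation fraction clips that tail fraction of pixels at each end before
#' equalizing (the pipeline default is 0, i.e. no clipping). A constant
#' image admits no remap and is returned unchanged.
#'
#' @param img Numeric matrix or `image_plane`.
#' @param saturation Fraction in `[0, 0.5)` of pixels to saturate at each
#'   extreme before equalization.
#' @param sqrt_variant Square-root the histogram counts before cumulation?
#' @return An `image_plane` spanning up to the full bit range.
#' @export
equalize_histogram <- function(img, saturation = 0, sqrt_variant = TRUE) {
  check_image(img)
  if (!is.numeric(saturation) || saturation < 0 || saturation >= 0.5) {
    stop("`saturation` must be in [0, 0.5)", call. = FALSE)
  }
  m <- as_pixel_matrix(img)
  if (max(m) == min(m)) {
    return(restamp(m, img))
  }
  if (saturation > 0) {
    qs <- stats::quantile(m, c(saturation, 1 - saturation), names = FALSE)
    m <- pmin(pmax(m, qs[1]), qs[2])
  }
  max_range <- bit_range(image_bit_depth(img))
  lev <- pmin(pmax(round(m), 0), max_range)
  counts <- tabulate(lev + 1L, nbins = max_range + 1L)
  wts <- if (sqrt_variant) sqrt(counts) else counts
  cdf <- cumsum(wts) / sum(wts)
  out <- matrix(max_range * cdf[lev + 1L], nrow(m), ncol(m))
  restamp(out, img)
}
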