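#' Threshold an image into a binary mask
#'
#' Computes a background threshold `T` and returns the mask `img > T`
#' (strict). Methods: `"isodata"` — the iterative intermeans fixed point,
#' where `T` converges to the midpoint of the mean intensity below and
#' above it; `"otsu"` — maximizes the between-class variance of the
#' intensity histogram; `"fixed"` — a user-supplied value. Intensities are
#' binned to the integer levels of the image's bit depth for the automatic
#' methods. A constant image admits no automatic threshold and errors.
#'
#' @param img Numeric matrix or `image_plane`.
#' @param method `"isodata"`, `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold used when `method = "fixed"`.
#' @return A [binary_mask()] with the chosen threshold in attribute
#'   `"threshold"`.
#' @export
#'
#' @examples
#' m <- matrix(c(50, 150), 2, 4)
#' auto_threshold(m, "fixed", fixed_value = 100)
auto_threshold <- function(img, method = c("isodata", "otsu", "fixed"),
                           fixed_value = NULL) {
  method <- match.arg(method)
  check_image(img)
  m <- as_pixel_matrix(img)
  if (method == "fixed") {
    if (is.null(fixed_value)) {
      stop("`fixed_value` must be supplied for method \"fixed\"",
        call. = FALSE
      )
    }
    thr <- fixed_value
  } else {
    if (max(m) == min(m)) {
      stop("no threshold definable for a constant image", call. = FALSE)
    }
    max_range <- bit_range(image_bit_depth(img))
    lev <- pmin(pmax(round(m), 0), max_range)
    counts <- as.numeric(tabulate(lev + 1L, nbins = max_range + 1L))
    vals <- as.numeric(seq.int(0L, max_range))
    thr <- switch(method,
      isodata = isodata_threshold(counts, vals),
      otsu = otsu_threshold(counts, vals)
    )
  }
  out <- binary_mask((m > thr) + 0L)
  attr(out, "threshold") <- thr
  out
}

# Iterative intermeans on a histogram: T_{k+1} = (mu_below + mu_above)/2,
# with below = levels <= T_k.
isodata_threshold <- function(counts, vals) {
  thr <- sum(counts * vals) / sum(counts)
  for (i in seq_len(1000L)) {
    below <- vals <= thr
    n_lo <- sum(counts[below])
    n_hi <- sum(counts[!below])
    if (n_lo == 0 || n_hi == 0) {
      break
    }
    mu_lo <- sum(counts[below] * vals[below]) / n_lo
    mu_hi <- sum(counts[!below] * vals[!below]) / n_hi
    new_thr <- (mu_lo + mu_hi) / 2
    if (abs(new_thr - thr) < 1e-9) {
      thr <- new_thr
      break
    }
    thr <- new_thr
  }
  thr
}

# Otsu's criterion: choose the level maximizing between-class variance.
otsu_threshold <- function(counts, vals) {
  n <- sum(counts)
  w0 <- cumsum(counts)
  mu0 <- cumsum(counts * vals)
  mu_t <- mu0[length(mu0)] / n
  valid <- w0 > 0 & w0 < n
  sigma_b <- rep(-Inf, length(vals))
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (n - w0[valid]))
  # ties (a flat maximizing plateau between well-separated modes) resolve
  # to the plateau mean, as in Otsu's original formulation
  mean(vals[sigma_b >= max(sigma_b) - 1e-9])
}
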