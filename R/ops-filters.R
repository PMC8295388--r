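# 3x3 correlation with edge-replicated borders.
conv3 <- function(m, kernel) {
  h <- nrow(m)
  w <- ncol(m)
  pad <- pad_replicate(m, 1L)
  out <- matrix(0, h, w)
  for (di in -1:1) {
    for (dj in -1:1) {
      wt <- kernel[di + 2L, dj + 2L]
      if (wt != 0) out <- out + wt * shifted_view(pad, h, w, 1L, di, dj)
    }
  }
  out
}

#' Sobel edge magnitude
#'
#' Per-pixel `sqrt(Gx^2 + Gy^2)` from the standard 3x3 Sobel kernels, with
#' borders handled by edge replication. This is the "find edges" step that
#' outlines cells in the transmitted-light channel.
#'
#' @param img Numeric matrix or `image_plane`, at least 3x3.
#' @return An `image_plane` of gradient magnitudes (may exceed the nominal
#'   bit range; the pipeline rescales downstream).
#' @export
sobel_edges <- function(img) {
  check_image(img, min_dim = 3L)
  m <- as_pixel_matrix(img)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) # d/dcol
  ky <- t(kx) # d/drow
  gx <- conv3(m, kx)
  gy <- conv3(m, ky)
  restamp(sqrt(gx^2 + gy^2), img, bit_depth = 16)
}

#' 3x3 mean smoothing
#'
#' Unweighted 3x3 mean with edge-replicated borders (the classical "smooth"
#' step).
#'
#' @param img Numeric matrix or `image_plane`.
#' @return An `image_plane` of the same shape.
#' @export
smooth_mean3 <- function(img) {
  check_image(img)
  m <- as_pixel_matrix(img)
  if (nrow(m) == 1L && ncol(m) == 1L) {
    return(restamp(m, img))
  }
  restamp(conv3(m, matrix(1, 3, 3)) / 9, img)
}

rank_offsets_apply <- function(m, offs, comb) {
  r <- max(abs(offs))
  h <- nrow(m)
  w <- ncol(m)
  pad <- pad_replicate(m, r)
  out <- NULL
  for (k in seq_len(nrow(offs))) {
    v <- shifted_view(pad, h, w, r, offs[k, 1L], offs[k, 2L])
    out <- if (is.null(out)) v else comb(out, v)
  }
  out
}

# Disk rank filter via per-row-offset 1-D window filters backed by a
# doubling (sparse) table; exact, and much faster than the offset loop for
# large radii. Only valid for disk structuring elements.
rank_disk_fast <- function(m, radius, comb) {
  r <- as.integer(floor(radius))
  h <- nrow(m)
  w <- ncol(m)
  pad <- pad_replicate(m, r)
  wp <- w + 2L * r
  di_seq <- seq.int(-r, r)
  halfw <- floor(sqrt(pmax(radius^2 - di_seq^2, 0)))
  kmax <- max(0L, floor(log2(2 * max(halfw) + 1)))
  tabs <- vector("list", kmax + 1L)
  tabs[[1L]] <- pad
  if (kmax > 0L) {
    for (k in seq_len(kmax)) {
      s <- 2L^(k - 1L)
      idx <- pmin(seq_len(wp) + s, wp)
      tabs[[k + 1L]] <- comb(tabs[[k]], tabs[[k]][, idx, drop = FALSE])
    }
  }
  center_cols <- r + seq_len(w)
  row_filt <- list()
  for (wv in unique(halfw)) {
    len <- 2L * wv + 1L
    k <- floor(log2(len))
    p <- 2L^k
    a <- tabs[[k + 1L]][, center_cols - wv, drop = FALSE]
    b <- tabs[[k + 1L]][, center_cols + wv - p + 1L, drop = FALSE]
    row_filt[[as.character(wv)]] <- comb(a, b)
  }
  center_rows <- r + seq_len(h)
  out <- NULL
  for (t in seq_along(di_seq)) {
    rf <- row_filt[[as.character(halfw[t])]]
    v <- rf[center_rows + di_seq[t], , drop = FALSE]
    out <- if (is.null(out)) v else comb(out, v)
  }
  out
}

#' Rank (minimum / maximum) filter
#'
#' Replaces each pixel by the minimum or maximum over its structuring
#' element neighborhood, with edge-replicated borders. Radius 0 is the
#' identity for both modes: the segmentation protocol applies a minimum
#' filter of radius 0 (a deliberate no-op, kept for fidelity to the
#' published parameter list) followed by a maximum filter of radius 5.
#'
#' @param img Numeric matrix or `image_plane`.
#' @param se A [structuring_element()] or a disk radius.
#' @param mode `"min"` or `"max"`.
#' @return An `image_plane` of the same shape.
#' @export
#'
#' @examples
#' m <- matrix(runif(25), 5, 5)
#' identical(as_pixel_matrix(rank_filter(m, se_disk(0), "min")), m) # TRUE
rank_filter <- function(img, se, mode = c("min", "max")) {
  mode <- match.arg(mode)
  check_image(img)
  se <- as_se(se)
  m <- as_pixel_matrix(img)
  if (floor(se$radius) == 0) {
    return(restamp(m, img))
  }
  comb <- if (mode == "max") pmax else pmin
  out <- if (se$shape == "disk" && floor(se$radius) >= 8) {
    rank_disk_fast(m, se$radius, comb)
  } else {
    rank_offsets_apply(m, se$offsets, comb)
  }
  restamp(out, img)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image by a
#' large disk (the flat-top approximation of the rolling-ball background)
#' and subtracts it, clipping at 0. Features smaller than the ball survive
#' at their original height above the local background; broad trends and
#' flat offsets are removed. A `"fixed"` method subtracting a constant
#' offset is also provided for the manual-threshold style of background
#' removal.
#'
#' @param img Numeric matrix or `image_plane`.
#' @param ball_radius Ball (disk) radius in pixels, >= 1. Default 50.
#' @param method `"rolling_ball"` (opening-based estimate) or `"fixed"`.
#' @param offset Constant to subtract when `method = "fixed"`.
#' @return An `image_plane` with the background estimate removed.
#' @export
subtract_background <- function(img, ball_radius = 50,
                                method = c("rolling_ball", "fixed"),
                                offset = 0) {
  method <- match.arg(method)
  check_image(img)
  m <- as_pixel_matrix(img)
  if (method == "fixed") {
    return(restamp(pmax(m - offset, 0), img))
  }
  if (ball_radius < 1) {
    stop("`ball_radius` must be >= 1", call. = FALSE)
  }
  se <- se_disk(ball_radius)
  bg <- rank_filter(rank_filter(m, se, "min"), se, "max")
  restamp(pmax(m - as_pixel_matrix(bg), 0), img)
}
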