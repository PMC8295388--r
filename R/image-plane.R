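#' Construct a single-channel image plane
#'
#' An `image_plane` is a numeric matrix of non-negative, finite intensities
#' (arbitrary units) with a nominal bit depth and a channel label. It is the
#' atom every image operator in the package consumes and returns. Rows index
#' image rows (origin top-left) and coordinates throughout the package are
#' 0-based `(row, col)` pairs; areas are in px^2.
#'
#' @param pixels Numeric matrix of intensities. Must be finite and >= 0, and
#'   within the range implied by `bit_depth` (<= 255 for 8-bit, <= 65535 for
#'   16-bit).
#' @param bit_depth Nominal bit depth, 8 or 16.
#' @param channel Channel label: one of `"DIC"`, `"blue"`, `"green"`,
#'   `"red"`, `"gray"`.
#'
#' @return A numeric matrix of class `image_plane` with attributes
#'   `bit_depth` and `channel`.
#' @export
#'
#' @examples
#' img <- image_plane(matrix(0:24, 5, 5), bit_depth = 8, channel = "gray")
#' dim(img)
image_plane <- function(pixels, bit_depth = 8, channel = "gray") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("all intensities must be >= 0", call. = FALSE)
  }
  if (!bit_depth %in% c(8, 16)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  if (max(pixels) > bit_range(bit_depth)) {
    stop("intensities exceed the range of a ", bit_depth, "-bit image",
      call. = FALSE
    )
  }
  channel <- match.arg(channel, c("DIC", "blue", "green", "red", "gray"))
  structure(unclass(pixels),
    bit_depth = bit_depth, channel = channel,
    class = c("image_plane", class(unclass(pixels)))
  )
}

#' @rdname image_plane
#' @param x Object to test or coerce.
#' @export
is_image_plane <- function(x) inherits(x, "image_plane")

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf(
    "<image_plane> %d x %d px, %d-bit, channel %s, range [%g, %g]\n",
    nrow(x), ncol(x), image_bit_depth(x), image_channel(x), min(x), max(x)
  ))
  invisible(x)
}

#' Bit depth and channel of an image plane
#'
#' Plain matrices are accepted everywhere an `image_plane` is; they default
#' to 8-bit, channel `"gray"`.
#'
#' @param img Matrix or `image_plane`.
#' @return `image_bit_depth()` returns 8 or 16; `image_channel()` a label.
#' @export
image_bit_depth <- function(img) {
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) 8 else bd
}

#' @rdname image_bit_depth
#' @export
image_channel <- function(img) {
  ch <- attr(img, "channel")
  if (is.null(ch)) "gray" else ch
}

bit_range <- function(bit_depth) if (bit_depth == 16) 65535 else 255

# Rewrap a result matrix with the metadata of a template image.
restamp <- function(pixels, template, bit_depth = image_bit_depth(template),
                    channel = image_channel(template)) {
  structure(pixels,
    bit_depth = bit_depth, channel = channel,
    class = c("image_plane", class(unclass(pixels)))
  )
}

as_pixel_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "bit_depth") <- NULL
  attr(m, "channel") <- NULL
  class(m) <- NULL
  dim(m) <- dim(img)
  m
}

check_image <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("expected a numeric matrix image", call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop("image must be at least ", min_dim, "x", min_dim, call. = FALSE)
  }
  invisible(img)
}

check_binary <- function(mask) {
  check_image(mask)
  if (!all(mask %in% c(0, 1))) {
    stop("mask must be strictly binary (0/1)", call. = FALSE)
  }
  invisible(mask)
}

#' Create a binary mask
#'
#' @param pixels Matrix of 0/1 values (logical matrices are coerced).
#' @return An integer 0/1 matrix of class `binary_mask`.
#' @export
binary_mask <- function(pixels) {
  if (is.logical(pixels)) pixels <- pixels + 0L
  check_binary(pixels)
  structure(pixels + 0L,
    dim = dim(pixels),
    class = c("binary_mask", "matrix", "array")
  )
}

# Pad a matrix by `r` pixels on every side with edge replication: the border
# rule used by all neighborhood filters in the package.
pad_replicate <- function(m, r) {
  if (r == 0L) {
    return(m)
  }
  h <- nrow(m)
  w <- ncol(m)
  ri <- c(rep(1L, r), seq_len(h), rep(h, r))
  ci <- c(rep(1L, r), seq_len(w), rep(w, r))
  m[ri, ci, drop = FALSE]
}

# View of a padded matrix shifted by (di, dj), cropped back to the original
# frame. `pad` is pad_replicate(m, r) and |di|, |dj| <= r.
shifted_view <- function(pad, h, w, r, di, dj) {
  pad[(r + di) + seq_len(h), (r + dj) + seq_len(w), drop = FALSE]
}
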