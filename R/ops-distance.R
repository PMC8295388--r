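#' Exact Euclidean distance transform of a binary mask
#'
#' For every foreground pixel, the Euclidean distance to the nearest
#' background pixel within the frame (background pixels map to 0). Computed
#' by the two-stage squared-distance transform: a 1-D pass along rows
#' followed by the lower-envelope-of-parabolas pass along columns, so the
#' result is exact, not a chamfer approximation. If the mask contains no
#' background at all, every pixel is assigned the frame diagonal (no
#' background exists to measure against).
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @return Numeric matrix of distances in pixels.
#' @export
distance_transform <- function(mask) {
  check_binary(mask)
  m <- as_pixel_matrix(mask)
  h <- nrow(m)
  w <- ncol(m)
  big <- h * h + w * w + 1
  # stage 1: distance to nearest background along each row
  d <- matrix(0, h, w)
  d[m == 1] <- big
  if (w > 1L) {
    for (j in 2:w) d[, j] <- pmin(d[, j], d[, j - 1L] + 1)
    for (j in (w - 1L):1L) d[, j] <- pmin(d[, j], d[, j + 1L] + 1)
  }
  d <- pmin(d, big)
  # stage 2: per column, squared lower envelope over row offsets
  f <- d^2
  out <- matrix(0, h, w)
  for (j in seq_len(w)) {
    out[, j] <- squared_edt_1d(pmin(f[, j], big))
  }
  sqrt(out)
}

# Felzenszwalb & Huttenlocher 1-D squared distance transform under
# quadratic cost: d[q] = min_v (q - v)^2 + f[v].
squared_edt_1d <- function(f) {
  n <- length(f)
  if (n == 1L) {
    return(f)
  }
  v <- integer(n)
  z <- numeric(n + 1L)
  d <- numeric(n)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}
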