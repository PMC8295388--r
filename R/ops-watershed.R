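# Morphological reconstruction by dilation of `marker` under `cap`
# (8-connected), by iterated 3x3 dilation clipped to the cap.
reconstruct_dilate <- function(marker, cap) {
  rec <- pmin(marker, cap)
  offs <- se_square(1)$offsets
  limit <- 2L * (nrow(rec) + ncol(rec))
  for (i in seq_len(limit)) {
    new <- pmin(rank_offsets_apply(rec, offs, pmax), cap)
    if (max(abs(new - rec)) < 1e-12) {
      return(new)
    }
    rec <- new
  }
  rec
}

# Watershed seed labels: h-maxima of the distance map D, i.e. connected
# regions where D stands at least `h` above the reconstruction of D - h,
# so that peaks within `h` of a saddle merge with the dominant peak.
watershed_seeds <- function(mask_m, d, h) {
  rec <- reconstruct_dilate(d - h, d)
  seeds <- (mask_m == 1) & (d - rec >= h - 1e-9)
  label_components(binary_mask(seeds + 0L), connectivity = 8)
}

#' Watershed splitting of touching particles
#'
#' Splits touching objects in a binary mask by flooding the negated
#' Euclidean distance transform from its regional maxima (peaks merged
#' within tolerance `h`), and inserts single-pixel-wide background lines
#' where basins from different seeds meet. Objects containing a single
#' seed are returned unchanged; an empty mask is returned unchanged.
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @param h Peak-merge tolerance, in intensity units of the distance map
#'   (default 1): distance-map maxima less prominent than `h` do not seed
#'   their own basin.
#' @param connectivity Neighborhood used during flooding (default 8).
#' @return A [binary_mask()] of the same shape with separating lines set
#'   to background.
#' @export
#'
#' @examples
#' m <- matrix(0L, 20, 32)
#' for (cc in list(c(10, 10), c(10, 22))) {
#'   for (i in 1:20) {
#'     for (j in 1:32) {
#'       if ((i - cc[1])^2 + (j - cc[2])^2 <= 64) m[i, j] <- 1L
#'     }
#'   }
#' }
#' n_components(label_components(binary_watershed(m)))
binary_watershed <- function(mask, h = 1, connectivity = 8) {
  check_binary(mask)
  m <- as_pixel_matrix(mask)
  if (!any(m == 1)) {
    return(binary_mask(m))
  }
  d <- distance_transform(m)
  seed_lab <- watershed_seeds(m, d, h)
  hh <- nrow(m)
  ww <- ncol(m)
  hp <- hh + 2L
  fg_idx <- which(m == 1)
  oi <- (fg_idx - 1L) %% hh + 1L
  oj <- (fg_idx - 1L) %/% hh + 1L
  pidx <- oj * hp + oi + 1L
  lab <- integer(hp * (ww + 2L))
  lab[pidx] <- seed_lab[fg_idx]
  offs <- if (connectivity == 8) {
    c(-1L, 1L, -hp, hp, -hp - 1L, -hp + 1L, hp - 1L, hp + 1L)
  } else {
    c(-1L, 1L, -hp, hp)
  }
  unl <- lab[pidx] == 0L
  depth <- d[fg_idx][unl]
  queue <- pidx[unl][order(depth, decreasing = TRUE)]
  # flood in order of decreasing depth; pixels reached before any labeled
  # neighbor are deferred and retried once flooding has caught up
  while (length(queue)) {
    remaining <- integer(0)
    progress <- FALSE
    for (p in queue) {
      nb <- lab[p + offs]
      pos <- nb[nb > 0L]
      if (!length(pos)) {
        remaining <- c(remaining, p)
        next
      }
      u <- unique(pos)
      lab[p] <- if (length(u) == 1L) u else -1L
      progress <- TRUE
    }
    if (!progress) break
    queue <- remaining
  }
  out <- matrix(0L, hh, ww)
  out[fg_idx] <- as.integer(lab[pidx] != -1L)
  binary_mask(out)
}
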