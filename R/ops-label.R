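#' Connected-component labeling with a particle size filter
#'
#' Labels connected foreground components 1..n in raster-scan discovery
#' order (top-left first, rows before columns), removes components whose
#' area falls outside `[min_area, max_area]`, and relabels the survivors
#' compactly. This is the particle-analysis step used both for cell ROIs
#' and for nucleus counting.
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_area,max_area Inclusive area window in px^2.
#' @return An integer matrix of class `labeled_mask` (0 = background,
#'   1..n = components) with the retained particle count in attribute
#'   `"count"` and per-label areas in attribute `"areas"`.
#' @export
#'
#' @examples
#' m <- matrix(0L, 5, 8)
#' m[2, 2:4] <- 1L # area 3
#' m[4:5, 5:8] <- 1L # area 8
#' n_components(label_components(m, min_area = 5))
label_components <- function(mask, connectivity = 8, min_area = 0,
                             max_area = Inf) {
  check_binary(mask)
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  if (min_area > max_area) {
    stop("`min_area` must be <= `max_area`", call. = FALSE)
  }
  m <- as_pixel_matrix(mask)
  h <- nrow(m)
  w <- ncol(m)
  hp <- h + 2L
  fg_idx <- which(m == 1)
  lab <- matrix(0L, h, w)
  if (length(fg_idx)) {
    oi <- (fg_idx - 1L) %% h + 1L
    oj <- (fg_idx - 1L) %/% h + 1L
    pidx <- oj * hp + oi + 1L # linear index in (h+2) x (w+2) padded frame
    pfg <- logical(hp * (w + 2L))
    pfg[pidx] <- TRUE
    plab <- integer(hp * (w + 2L))
    offs <- if (connectivity == 8) {
      c(-1L, 1L, -hp, hp, -hp - 1L, -hp + 1L, hp - 1L, hp + 1L)
    } else {
      c(-1L, 1L, -hp, hp)
    }
    ord <- pidx[order(oi, oj)] # raster-scan discovery order
    n_lab <- 0L
    for (p in ord) {
      if (plab[p] != 0L) next
      n_lab <- n_lab + 1L
      plab[p] <- n_lab
      frontier <- p
      while (length(frontier)) {
        nb <- rep(frontier, each = length(offs)) +
          rep(offs, times = length(frontier))
        nb <- unique(nb[pfg[nb] & plab[nb] == 0L])
        if (!length(nb)) break
        plab[nb] <- n_lab
        frontier <- nb
      }
    }
    lab[fg_idx] <- plab[pidx]
  }
  n_all <- max(lab, 0L)
  areas <- if (n_all > 0L) tabulate(lab[lab > 0L], nbins = n_all) else integer(0)
  keep <- which(areas >= min_area & areas <= max_area)
  remap <- integer(n_all)
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, h, w)
  if (n_all > 0L) {
    pos <- lab > 0L
    out[pos] <- remap[lab[pos]]
  }
  structure(out,
    count = length(keep), areas = areas[keep],
    class = c("labeled_mask", "matrix", "array")
  )
}

#' @rdname label_components
#' @param labels A `labeled_mask`.
#' @export
n_components <- function(labels) {
  cnt <- attr(labels, "count")
  if (is.null(cnt)) max(labels, 0L) else cnt
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf(
    "<labeled_mask> %d x %d px, %d component(s)\n",
    nrow(x), ncol(x), n_components(x)
  ))
  invisible(x)
}
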