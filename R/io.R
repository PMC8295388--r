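#' Read and write image planes as TIFF
#'
#' Thin wrappers around the `tiff` package that preserve the package's
#' intensity convention (integer a.u. on the nominal bit range).
#' `read_image_tiff()` returns one `image_plane` per page for multi-page
#' files (a list for `all = TRUE`); an RGB page is returned as a named
#' list of the three planes. `write_image_tiff()` stores 8- or 16-bit
#' grayscale.
#'
#' @param path File path.
#' @param all Return all pages of a multi-page TIFF?
#' @param channel Channel label stamped on the result.
#' @return An `image_plane`, or a list of them.
#' @export
read_image_tiff <- function(path, all = FALSE, channel = "gray") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  wrap <- function(m) {
    if (length(dim(m)) == 3L) {
      bd <- if (max(m) > 255) 16 else 8
      return(list(
        r = image_plane(m[, , 1], bd, "gray"),
        g = image_plane(m[, , 2], bd, "gray"),
        b = image_plane(m[, , 3], bd, "gray")
      ))
    }
    bd <- if (max(m) > 255) 16 else 8
    image_plane(m, bd, channel)
  }
  out <- lapply(pages, wrap)
  if (all) out else out[[1]]
}

#' @rdname read_image_tiff
#' @param img Numeric matrix or `image_plane` (values are rounded and
#'   clipped to the bit range).
#' @param bit_depth 8 or 16.
#' @export
write_image_tiff <- function(img, path, bit_depth = image_bit_depth(img)) {
  m <- pmin(pmax(round(as_pixel_matrix(img)), 0), bit_range(bit_depth))
  tiff::writeTIFF(m / bit_range(bit_depth), path,
    bits.per.sample = bit_depth
  )
  invisible(path)
}

#' Export a mask or label image as PNG
#'
#' Binary masks are written as black/white; labeled masks as gray levels
#' proportional to the label (for quick visual inspection).
#'
#' @param mask A [binary_mask()] or `labeled_mask`.
#' @param path File path.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_pixel_matrix(mask)
  mx <- max(m, 1)
  png::writePNG(m / mx, path)
  invisible(path)
}

#' Write a scene to a directory
#'
#' Writes the four channels as single-page TIFFs (`DIC.tif`, `blue.tif`,
#' `green.tif`, `red.tif`) plus the ground truth as `truth.csv`.
#'
#' @param scene A `synthetic_scene` from [generate_scene()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(scene$channels)) {
    write_image_tiff(scene$channels[[nm]], file.path(dir, paste0(nm, ".tif")))
  }
  readr::write_csv(scene$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_scene
#' @return `read_scene_channels()` returns a named list of `image_plane`s.
#' @export
read_scene_channels <- function(dir) {
  chans <- c("DIC", "blue", "green", "red")
  out <- list()
  for (nm in chans) {
    f <- file.path(dir, paste0(nm, ".tif"))
    if (file.exists(f)) out[[nm]] <- read_image_tiff(f, channel = if (nm == "DIC") "DIC" else nm)
  }
  if (!length(out)) stop("no channel TIFFs found in ", dir, call. = FALSE)
  out
}
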