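#' Grayscale and binary morphology
#'
#' Erosion is the rank-minimum over the structuring element, dilation the
#' rank-maximum, and closing a dilation followed by an erosion with the
#' same element. On binary masks these reduce to the usual set operations;
#' closing fills holes and gaps smaller than the element and is extensive
#' (`close(x) >= x` pixelwise). The segmentation protocol applies, in
#' order, a closing, a dilation and an erosion to consolidate cell masks.
#'
#' @param img Numeric matrix, `image_plane` or [binary_mask()].
#' @param se A [structuring_element()] or disk radius (pipeline default:
#'   disk of radius 3).
#' @param op `"erode"`, `"dilate"` or `"close"`.
#' @return Same type as the input (binary masks stay binary).
#' @export
#'
#' @examples
#' sq <- matrix(0L, 9, 9)
#' sq[3:7, 3:7] <- 1L
#' sq[5, 5] <- 0L # 1-px hole
#' filled <- gray_morphology(binary_mask(sq), se_disk(2), "close")
#' filled[5, 5] # 1
gray_morphology <- function(img, se = se_disk(3), op = c("erode", "dilate", "close")) {
  op <- match.arg(op)
  se <- as_se(se)
  was_mask <- inherits(img, "binary_mask")
  out <- switch(op,
    erode = rank_filter(img, se, "min"),
    dilate = rank_filter(img, se, "max"),
    close = rank_filter(rank_filter(img, se, "max"), se, "min")
  )
  if (was_mask) binary_mask(as_pixel_matrix(out) + 0L) else out
}
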