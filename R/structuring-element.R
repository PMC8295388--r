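#' Structuring elements for rank and morphological filters
#'
#' A disk of radius `r` contains exactly the integer offsets `(di, dj)` with
#' `di^2 + dj^2 <= r^2`; a square of radius `r` contains all offsets with
#' `max(|di|, |dj|) <= r`. Radius 0 is the single center pixel for both
#' shapes, so any filter built on it is the identity. Membership uses
#' center distance <= radius with no rasterization tolerance, which makes a
#' radius-1 disk the 5-pixel cross.
#'
#' @param radius Non-negative radius in pixels.
#' @param shape `"disk"` or `"square"`.
#' @return An object of class `structuring_element` holding the offset
#'   matrix (`offsets`, two columns `di`, `dj`), `shape` and `radius`.
#' @export
#'
#' @examples
#' nrow(se_disk(1)$offsets) # the 5-pixel cross
#' nrow(se_square(1)$offsets) # the full 3x3 block
structuring_element <- function(radius, shape = c("disk", "square")) {
  shape <- match.arg(shape)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    stop("`radius` must be a single non-negative number", call. = FALSE)
  }
  r <- as.integer(floor(radius))
  d <- seq.int(-r, r)
  grid <- expand.grid(di = d, dj = d)
  keep <- if (shape == "disk") {
    grid$di^2 + grid$dj^2 <= radius^2
  } else {
    rep(TRUE, nrow(grid))
  }
  offs <- as.matrix(grid[keep, , drop = FALSE])
  rownames(offs) <- NULL
  structure(
    list(shape = shape, radius = radius, offsets = offs),
    class = "structuring_element"
  )
}

#' @rdname structuring_element
#' @export
se_disk <- function(radius) structuring_element(radius, "disk")

#' @rdname structuring_element
#' @export
se_square <- function(radius) structuring_element(radius, "square")

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf(
    "<structuring_element> %s, radius %g (%d offsets)\n",
    x$shape, x$radius, nrow(x$offsets)
  ))
  invisible(x)
}

as_se <- function(se) {
  if (inherits(se, "structuring_element")) {
    return(se)
  }
  if (is.numeric(se) && length(se) == 1L) {
    return(se_disk(se))
  }
  stop("`se` must be a structuring_element or a disk radius", call. = FALSE)
}
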