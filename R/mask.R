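#' Binary masks
#'
#' Masks are plain logical matrices with `H` rows and `W` columns. A point
#' (x, y) means x = column index and y = row index, both 0-based, with y
#' increasing downward; the pixel at matrix cell `[y + 1, x + 1]` has its
#' center at coordinate (x, y).
#'
#' @param m a logical or numeric matrix; numeric values are thresholded at 0.5
#'   (PNG files store foreground as 255, read by [png::readPNG()] as 1).
#' @return a logical matrix.
#' @export
as_mask <- function(m) {
  if (is.logical(m) && is.matrix(m)) return(m)
  if (!is.matrix(m) && !is.array(m)) abort_bs("mask must be a matrix", "usage_error")
  if (length(dim(m)) == 3L) m <- m[, , 1L]  # grayscale stored with channels
  matrix(as.numeric(m) >= 0.5, nrow = nrow(m), ncol = ncol(m))
}

#' Read a mask from an 8-bit grayscale PNG
#'
#' Foreground is any pixel value >= 128 (0.5 after png's 0..1 scaling).
#'
#' @param path PNG file path.
#' @return a logical mask matrix.
#' @export
read_mask <- function(path) {
  as_mask(png::readPNG(path))
}

#' Write a mask to an 8-bit grayscale PNG (0 background, 255 foreground)
#'
#' @param mask logical mask matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Morphologically smooth a mask
#'
#' Opening followed by closing with a disc structuring element, removing
#' boundary spikes and thin intrusions before curve fitting. Radius 0 is the
#' identity.
#'
#' @param mask logical mask matrix.
#' @param radius disc radius in pixels, >= 0.
#' @return the smoothed logical mask.
#' @export
smooth_mask <- function(mask, radius) {
  mask <- as_mask(mask)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    abort_bs("radius must be a single number >= 0", "usage_error")
  }
  if (radius == 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m <- EBImage::closing(EBImage::opening(m, brush), brush)
  out <- m >= 0.5
  if (!any(out)) {
    abort_bs("morphological smoothing erased the object", "degenerate_object_error")
  }
  out
}

# Largest connected foreground component (ties: earliest raster-scan label),
# holes filled. Returns a logical matrix.
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  if (max(lab) < 1) abort_bs("mask has no foreground pixels", "degenerate_object_error")
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)  # bwlabel labels in raster order, so first max wins
  comp <- lab == keep
  EBImage::fillHull(matrix(as.numeric(comp), nrow(comp), ncol(comp))) >= 0.5
}
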