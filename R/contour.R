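#' Extract the closed boundary of the largest object in a mask
#'
#' Traces the 0.5 iso-level between foreground and background (marching
#' squares via [grDevices::contourLines()]), giving a sub-pixel closed
#' boundary. Preprocessing keeps the largest connected component (ties broken
#' by earliest raster-scan position) and fills holes; the mask is padded by
#' one background pixel so full-frame objects still close. The returned
#' contour is oriented so traversal visits the top, leftmost, bottom and
#' rightmost points in that cyclic order (negative shoelace sum in y-down
#' image coordinates), with no consecutive duplicate points and the closing
#' point dropped.
#'
#' @param mask a logical mask matrix (see [as_mask()]).
#' @return a numeric matrix with columns `x`, `y`, one boundary point per row.
#' @export
#' @examples
#' m <- matrix(FALSE, 20, 20); m[8:13, 5:14] <- TRUE
#' head(extract_contour(m))
extract_contour <- function(mask) {
  mask <- as_mask(mask)
  comp <- largest_component(mask)  # errors on empty mask
  H <- nrow(comp); W <- ncol(comp)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- comp
  # contourLines wants z[i, j] at (x[i], y[j]); our matrix is [y + 1, x + 1]
  cl <- grDevices::contourLines(x = -1:W, y = -1:H, z = t(pad), levels = 0.5)
  if (length(cl) == 0L) abort_bs("no iso-contour found", "degenerate_object_error")
  ln <- cl[[which.max(vapply(cl, function(l) length(l$x), numeric(1)))]]
  pts <- cbind(x = ln$x, y = ln$y)
  n <- nrow(pts)
  if (n > 1L && all(pts[1, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  dup <- c(FALSE, rowSums(abs(diff(pts))) == 0)
  pts <- pts[!dup, , drop = FALSE]
  if (nrow(pts) < 4L) {
    abort_bs("object boundary has fewer than 4 points", "degenerate_object_error")
  }
  orient_contour(pts)
}

# Shoelace sum; negative = top -> leftmost -> bottom -> rightmost traversal
# in y-down image coordinates.
shoelace <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y)
}

orient_contour <- function(pts) {
  if (shoelace(pts) > 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

#' Locate the four extreme points of a contour
#'
#' The topmost, leftmost, bottommost and rightmost boundary points. When an
#' extreme is attained by several points (a flat side), ties resolve to the
#' corner reading: top takes the top-left point (min y, then min x), leftmost
#' the bottom-left (min x, then max y), bottom the bottom-right (max y, then
#' max x), rightmost the top-right (max x, then min y) — the four corners of
#' the bounding box, traversed consistently with contour orientation.
#'
#' @param contour a contour matrix from [extract_contour()].
#' @return a list with `points` (4 x 2 matrix, rows `top`, `left`, `bottom`,
#'   `right`) and `indices` (their 1-based row indices on the contour, in
#'   cyclic traversal order starting at `top`).
#' @export
find_extreme_points <- function(contour) {
  contour <- as.matrix(contour)
  x <- contour[, 1]; y <- contour[, 2]
  tol <- 1e-9
  pick <- function(primary, p_min, secondary, s_min) {
    cand <- if (p_min) which(primary <= min(primary) + tol) else
                       which(primary >= max(primary) - tol)
    cand[if (s_min) which.min(secondary[cand]) else which.max(secondary[cand])]
  }
  idx <- c(top    = pick(y, TRUE,  x, TRUE),
           left   = pick(x, TRUE,  y, FALSE),
           bottom = pick(y, FALSE, x, FALSE),
           right  = pick(x, FALSE, y, TRUE))
  if (length(unique(idx)) != 4L) {
    abort_bs("fewer than 4 distinct extreme points", "degenerate_object_error")
  }
  # cyclic order along the traversal, anchored at top
  rel <- (idx - idx[["top"]]) %% nrow(contour)
  if (any(order(rel) != 1:4)) {
    abort_bs("extreme points out of traversal order (degenerate shape)",
             "degenerate_object_error")
  }
  pts <- contour[idx, , drop = FALSE]
  rownames(pts) <- names(idx)
  list(points = pts, indices = idx)
}

#' Split a contour into four arcs at its extreme points
#'
#' Arcs run in traversal order from one extreme point to the next, inclusive
#' of both endpoints, so consecutive arcs share exactly one point and
#' concatenating the arcs minus the shared endpoints reproduces the contour.
#'
#' @param contour a contour matrix.
#' @param extremes result of [find_extreme_points()] on that contour.
#' @return a list of four point matrices (top->left, left->bottom,
#'   bottom->right, right->top).
#' @export
split_contour <- function(contour, extremes = find_extreme_points(contour)) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  idx <- extremes$indices
  if (length(unique(idx)) != 4L) {
    abort_bs("extreme indices must be distinct", "degenerate_object_error")
  }
  lapply(1:4, function(k) {
    i0 <- idx[k]; i1 <- idx[(k %% 4L) + 1L]
    span <- if (i1 > i0) i0:i1 else c(i0:n, 1:i1)
    contour[span, , drop = FALSE]
  })
}

#' Write a contour to CSV
#'
#' Plain CSV with header `x,y`, one point per row, full float precision.
#'
#' @param contour a contour matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as.data.frame(as.matrix(contour))[, 1:2] |>
                     stats::setNames(c("x", "y")),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a contour from CSV
#' @param path CSV file with columns `x`, `y`.
#' @return a contour matrix.
#' @export
read_contour_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d))) abort_bs("contour CSV needs x,y columns", "usage_error")
  cbind(x = d$x, y = d$y)
}

# Resample a polyline at k index-uniform positions (linear interpolation on
# the point index), keeping the original endpoints.
resample_polyline <- function(pts, k) {
  m <- nrow(pts)
  if (m == k) return(pts)
  at <- seq(1, m, length.out = k)
  cbind(x = stats::approx(seq_len(m), pts[, 1], xout = at)$y,
        y = stats::approx(seq_len(m), pts[, 2], xout = at)$y)
}
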