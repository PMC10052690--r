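#' Shape codes
#'
#' A shape code is the flat regression-target vector of a piecewise Bezier
#' boundary: the four extreme points in traversal order (top, leftmost,
#' bottom, rightmost) followed by the interior control points of the four
#' segments, segment by segment, each point stored as (x, y). With the
#' default degree 5 that is ne = 4 extreme points and nc = 16 interior
#' control points: a 40-value vector.
#'
#' @param values numeric vector of length `2 * (4 + 4 * (degree - 1))`.
#' @param degree common degree of the four segments (default 5).
#' @return an object of class `shape_code`.
#' @export
shape_code <- function(values, degree = 5L) {
  degree <- as.integer(degree)
  if (degree < 2L) abort_bs("piecewise codec needs degree >= 2", "usage_error")
  ne <- 4L; nc <- 4L * (degree - 1L)
  values <- as.numeric(values)
  if (length(values) != 2L * (ne + nc) || anyNA(values) || !all(is.finite(values))) {
    abort_bs(sprintf("shape code must hold %d finite values", 2L * (ne + nc)),
             "codec_error")
  }
  structure(list(values = values, ne = ne, nc = nc, degree = degree),
            class = "shape_code")
}

#' @export
print.shape_code <- function(x, ...) {
  cat(sprintf("<shape_code> degree %d, ne = %d, nc = %d, %d values\n",
              x$degree, x$ne, x$nc, length(x$values)))
  invisible(x)
}

# 20 code points (default degree) as a matrix: rows 1..4 extremes, then
# 4 + (k-1)*(degree-1) + j = interior point j of segment k.
code_points <- function(code) {
  matrix(code$values, ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y")))
}

points_to_code <- function(pts, degree = 5L) {
  shape_code(as.numeric(t(pts)), degree = degree)
}

#' Split a shape code into its four Bezier segments
#'
#' Segment k runs from extreme point k to extreme point k + 1 (cyclically),
#' with the code's interior control points in between.
#'
#' @param code a [shape_code()].
#' @return a list of four [bezier_segment()] objects.
#' @export
code_segments <- function(code) {
  stopifnot(inherits(code, "shape_code"))
  pts <- code_points(code)
  d <- code$degree
  lapply(1:4, function(k) {
    interior <- pts[4L + (k - 1L) * (d - 1L) + seq_len(d - 1L), , drop = FALSE]
    bezier_segment(rbind(pts[k, ], interior, pts[(k %% 4L) + 1L, ]), degree = d)
  })
}

# Moore-Penrose pseudo-inverse via SVD, relative singular-value cutoff.
pinv_svd <- function(A, rcond = 1e-10) {
  s <- svd(A)
  keep <- s$d > rcond * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit one Bezier segment to a boundary arc
#'
#' The first and last control points are fixed to the arc endpoints (they are
#' extreme points of the shape); the `degree - 1` interior control points
#' solve the linear least-squares system in the Bernstein basis via the
#' Moore-Penrose pseudo-inverse, with both coordinates sharing one system.
#' The i-th arc point is assigned parameter `t_i = (i - 1) / (m - 1)`
#' (index-uniform); `parametrization = "chord"` switches to normalized
#' cumulative chord length. Arcs with fewer than `degree + 1` points are
#' linearly resampled to `2 * (degree + 1)` points first.
#'
#' @param arc numeric matrix of ordered boundary points (columns x, y).
#' @param degree Bezier degree (default 5).
#' @param parametrization `"index"` (default) or `"chord"`.
#' @return a [bezier_segment()] whose endpoints equal the arc endpoints.
#' @export
fit_segment <- function(arc, degree = 5L,
                        parametrization = c("index", "chord")) {
  parametrization <- match.arg(parametrization)
  arc <- as.matrix(arc)
  n <- as.integer(degree)
  if (nrow(arc) < 2L) abort_bs("arc needs at least 2 points", "usage_error")
  if (nrow(arc) < n + 1L) arc <- resample_polyline(arc, 2L * (n + 1L))
  m <- nrow(arc)
  tt <- if (parametrization == "index") {
    seq(0, 1, length.out = m)
  } else {
    cl <- c(0, cumsum(sqrt(rowSums(diff(arc)^2))))
    if (cl[m] == 0) seq(0, 1, length.out = m) else cl / cl[m]
  }
  B <- bernstein_basis(n, tt)
  P0 <- arc[1, ]; Pn <- arc[m, ]
  inner <- 2:(m - 1L)
  A <- B[inner, 2:n, drop = FALSE]
  b <- arc[inner, , drop = FALSE] -
    outer(B[inner, 1L], P0) - outer(B[inner, n + 1L], Pn)
  interior <- pinv_svd(A) %*% b
  bezier_segment(rbind(P0, interior, Pn), degree = n)
}

#' Encode a binary mask as a piecewise Bezier shape code
#'
#' Pipeline: optional morphological smoothing, sub-pixel contour extraction,
#' extreme-point location, split into four arcs, constrained least-squares
#' fit of each arc, packing into the flat code vector. Deterministic.
#'
#' @param mask a logical mask matrix (see [as_mask()]).
#' @param degree Bezier degree per segment (default 5, giving 40 values).
#' @param smooth_radius disc radius for [smooth_mask()]; 0 (default) skips it.
#' @param parametrization passed to [fit_segment()].
#' @return a [shape_code()].
#' @export
#' @examples
#' m <- matrix(FALSE, 64, 64); m[20:45, 15:50] <- TRUE
#' code <- encode_mask(m)
#' length(code$values)  # 40
encode_mask <- function(mask, degree = 5L, smooth_radius = 0,
                        parametrization = c("index", "chord")) {
  parametrization <- match.arg(parametrization)
  mask <- smooth_mask(as_mask(mask), smooth_radius)
  contour <- extract_contour(mask)
  ex <- find_extreme_points(contour)
  arcs <- split_contour(contour, ex)
  segs <- lapply(arcs, fit_segment, degree = degree,
                 parametrization = parametrization)
  d <- as.integer(degree)
  interior <- do.call(rbind, lapply(segs, function(s)
    s$control_points[2:d, , drop = FALSE]))
  points_to_code(rbind(ex$points, interior), degree = d)
}

#' Decode a shape code into a dense closed contour
#'
#' Each segment is sampled at a uniform parameter grid of
#' `samples_per_segment` points; shared endpoints are not duplicated, so the
#' contour has `4 * (samples_per_segment - 1)` points.
#'
#' @param code a [shape_code()].
#' @param samples_per_segment points per segment, >= 2 (default 72).
#' @return a contour matrix (columns x, y).
#' @export
decode_code <- function(code, samples_per_segment = 72L) {
  stopifnot(inherits(code, "shape_code"))
  S <- as.integer(samples_per_segment)
  if (S < 2L) abort_bs("samples_per_segment must be >= 2", "usage_error")
  ts <- seq(0, 1, length.out = S)
  do.call(rbind, lapply(code_segments(code), function(seg)
    evaluate_bernstein(seg, ts)[-S, , drop = FALSE]))
}

#' Rescale a shape code to a different raster resolution
#'
#' Bezier curves are affine-equivariant, so changing resolution is pure
#' coordinate scaling of the code.
#'
#' @param code a [shape_code()].
#' @param sx,sy scale factors for x and y (sy defaults to sx).
#' @return the scaled [shape_code()].
#' @export
scale_code <- function(code, sx, sy = sx) {
  pts <- code_points(code)
  pts[, 1] <- pts[, 1] * sx
  pts[, 2] <- pts[, 2] * sy
  points_to_code(pts, degree = code$degree)
}

#' Write a shape code to JSON
#'
#' Format: `{"ne": 4, "nc": 16, "degree": 5,
#' "order": "extremes_then_controls", "values": [x0, y0, ...]}` with floats
#' at full precision.
#'
#' @param code a [shape_code()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shape_code <- function(code, path) {
  stopifnot(inherits(code, "shape_code"))
  jsonlite::write_json(
    list(ne = code$ne, nc = code$nc, degree = code$degree,
         order = "extremes_then_controls", values = code$values),
    path, auto_unbox = TRUE, digits = I(17))  # 17 sig. digits: lossless doubles
  invisible(path)
}

#' Read a shape code from JSON
#'
#' Rejects files whose `values` length does not match `ne`, `nc` and `degree`.
#'
#' @param path JSON file written by [write_shape_code()].
#' @return a [shape_code()].
#' @export
read_shape_code <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("ne", "nc", "degree", "values")
  if (!all(need %in% names(obj))) abort_bs("malformed shape-code JSON", "codec_error")
  if (obj$ne != 4L || obj$nc != 4L * (obj$degree - 1L)) {
    abort_bs("shape-code JSON has inconsistent ne/nc/degree", "codec_error")
  }
  shape_code(obj$values, degree = obj$degree)
}
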