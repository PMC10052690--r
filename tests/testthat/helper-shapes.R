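# Shared fixture builders: everything is generated in code at test time.

# filled axis-aligned rectangle mask; x/y are 0-based inclusive pixel ranges
rect_mask <- function(H, W, x0, x1, y0, y1) {
  m <- matrix(FALSE, H, W)
  m[(y0:y1) + 1L, (x0:x1) + 1L] <- TRUE
  m
}

disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(0:(W - 1L), each = H), H, W)
  ys <- matrix(rep(0:(H - 1L), times = W), H, W)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

random_segment <- function(degree, scale = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bezier_segment(matrix(runif(2 * (degree + 1), 0, scale), ncol = 2),
                 degree = degree)
}

random_code <- function(seed = NULL, scale = 100) {
  if (!is.null(seed)) set.seed(seed)
  shape_code(runif(40, 0, scale))
}

# closed polyline perimeter
perimeter <- function(pts) {
  closed <- rbind(pts, pts[1, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

# brute-force symmetric Hausdorff oracle (all-pairs distances)
hausdorff_brute <- function(a, b) {
  d2 <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))
}

# point-in-convex-hull oracle: all cross products with hull edges one-signed
in_convex_hull <- function(pt, hull_pts, tol = 1e-9) {
  h <- hull_pts[grDevices::chull(hull_pts), , drop = FALSE]
  n <- nrow(h)
  s <- vapply(seq_len(n), function(i) {
    a <- h[i, ]; b <- h[(i %% n) + 1L, ]
    (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
  }, numeric(1))
  all(s >= -tol) || all(s <= tol)
}
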