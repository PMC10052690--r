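#' Specification for a synthetic single-object mask
#'
#' The generator emulates the region-of-interest regimes seen in clinical
#' segmentation datasets (lesion areas from a few hundred to a few tens of
#' thousands of pixels) with five shape families: ellipses, superellipses,
#' star-convex Fourier blobs (radius \eqn{r(\theta) = r_0 (1 + \sum_h a_h
#' \cos(h\theta + \phi_h))} with \eqn{|a_h| \le 0.2/h}, keeping the radius
#' positive), dumbbells (two discs joined by a neck — a deliberately
#' non-star-convex stressor), and axis-aligned squares.
#'
#' @param kind one of `"ellipse"`, `"superellipse"`, `"fourier_blob"`,
#'   `"dumbbell"`, `"square"`.
#' @param area target foreground area in pixels (>= 50; realized area is
#'   within 15%).
#' @param size image dimensions `c(H, W)` (default 256 x 256).
#' @param smoothness number of Fourier harmonics for blobs (default 4;
#'   harmonics h = 2..smoothness+1 are used, h = 1 being mostly a centroid
#'   shift rather than a shape feature).
#' @param seed RNG seed making the shape deterministic.
#' @return an object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("ellipse", "superellipse", "fourier_blob",
                                "dumbbell", "square"),
                       area, size = c(256L, 256L), smoothness = 4L,
                       seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(area) || length(area) != 1L || area < 50) {
    abort_bs("area must be a single number >= 50", "spec_error")
  }
  if (length(size) != 2L || any(size < 8)) {
    abort_bs("size must be c(H, W) with both >= 8", "spec_error")
  }
  structure(list(kind = kind, area = area, size = as.integer(size),
                 smoothness = as.integer(smoothness), seed = seed),
            class = "shape_spec")
}

# pixel-center coordinate grids for an H x W frame
center_grid <- function(H, W) {
  list(x = matrix(rep(0:(W - 1L), each = H), H, W),
       y = matrix(rep(0:(H - 1L), times = W), H, W))
}

# area factor of the unit dumbbell (discs r=1 at (+-1.6, 0), neck |y|<=0.35):
# 2*pi + 3.2*0.7 - 2*(h*sqrt(1-h^2) + asin(h)) with h = 0.35.
dumbbell_area_factor <- function() {
  h <- 0.35
  2 * pi + 3.2 * 0.7 - 2 * (h * sqrt(1 - h^2) + asin(h))
}

#' Generate a synthetic single-object binary mask
#'
#' Deterministic given `spec$seed`. Shapes are rasterized by testing pixel
#' centers against the analytic inside predicate, so the traced 0.5
#' iso-contour matches the analytic boundary to sub-pixel accuracy. For
#' star-convex kinds the analytic boundary polyline (720 points) is attached
#' as attribute `"contour"`. Errors with class `spec_error` when the shape
#' cannot fit the frame.
#'
#' @param spec a [shape_spec()].
#' @return a logical mask matrix, with attribute `contour` where available.
#' @export
#' @examples
#' m <- generate_mask(shape_spec("fourier_blob", area = 10000, seed = 7))
#' sum(m)
generate_mask <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  H <- spec$size[1]; W <- spec$size[2]
  cx0 <- (W - 1) / 2; cy0 <- (H - 1) / 2
  jit <- 0.05 * min(H, W)
  cx <- cx0 + stats::runif(1, -jit, jit)
  cy <- cy0 + stats::runif(1, -jit, jit)
  g <- center_grid(H, W)
  theta_grid <- seq(0, 2 * pi, length.out = 721L)[-721L]

  radial <- NULL  # r(theta) for star-convex kinds
  if (spec$kind == "ellipse" || spec$kind == "superellipse") {
    aspect <- stats::runif(1, 0.6, 1.6)
    rot <- stats::runif(1, 0, pi)
    p <- if (spec$kind == "ellipse") 2 else stats::runif(1, 2.5, 4)
    # |u/a|^p + |v/b|^p <= 1 has area 4ab * gamma(1+1/p)^2 / gamma(1+2/p)
    gfac <- 4 * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)
    a <- sqrt(spec$area * aspect / gfac)
    b <- a / aspect
    radial <- function(theta) {
      co <- cos(theta - rot); si <- sin(theta - rot)
      (abs(co / a)^p + abs(si / b)^p)^(-1 / p)
    }
  } else if (spec$kind == "fourier_blob") {
    hmax <- max(spec$smoothness, 1L)
    hs <- seq(2L, 1L + hmax)
    amp <- stats::runif(hmax, -1, 1) * 0.2 / hs
    phase <- stats::runif(hmax, 0, 2 * pi)
    r0 <- sqrt(spec$area / (pi * (1 + sum(amp^2) / 2)))
    radial <- function(theta) {
      f <- rep(1, length(theta))
      for (i in seq_along(hs)) f <- f + amp[i] * cos(hs[i] * theta + phase[i])
      r0 * f
    }
  } else if (spec$kind == "square") {
    s <- sqrt(spec$area)
    half <- s / 2
    if (cx - half < 1 || cx + half > W - 2 || cy - half < 1 || cy + half > H - 2) {
      abort_bs("square does not fit the frame", "spec_error")
    }
    mask <- abs(g$x - cx) <= half & abs(g$y - cy) <= half
    return(finish_mask(mask, spec, contour = NULL))
  } else { # dumbbell
    r <- sqrt(spec$area / dumbbell_area_factor())
    if (cx - 2.6 * r < 1 || cx + 2.6 * r > W - 2 || cy - r < 1 || cy + r > H - 2) {
      abort_bs("dumbbell does not fit the frame", "spec_error")
    }
    dx <- g$x - cx; dy <- g$y - cy
    mask <- ((dx - 1.6 * r)^2 + dy^2 <= r^2) |
            ((dx + 1.6 * r)^2 + dy^2 <= r^2) |
            (abs(dx) <= 1.6 * r & abs(dy) <= 0.35 * r)
    return(finish_mask(mask, spec, contour = NULL))
  }

  rmax <- max(radial(theta_grid))
  if (cx - rmax < 1 || cx + rmax > W - 2 || cy - rmax < 1 || cy + rmax > H - 2) {
    abort_bs("shape does not fit the frame at this area target", "spec_error")
  }
  dx <- g$x - cx; dy <- g$y - cy
  mask <- sqrt(dx^2 + dy^2) <= radial(atan2(dy, dx))
  rr <- radial(theta_grid)
  contour <- cbind(x = cx + rr * cos(theta_grid), y = cy + rr * sin(theta_grid))
  finish_mask(mask, spec, contour = orient_contour(contour))
}

finish_mask <- function(mask, spec, contour) {
  if (sum(mask) < 4L) abort_bs("generated mask degenerate", "spec_error")
  realized <- sum(mask)
  if (abs(realized - spec$area) > 0.15 * spec$area) {
    abort_bs(sprintf("realized area %d misses target %g by more than 15%%",
                     realized, spec$area), "spec_error")
  }
  if (!is.null(contour)) attr(mask, "contour") <- contour
  attr(mask, "spec") <- spec
  mask
}

#' Generate a battery of synthetic masks in a size regime
#'
#' Regimes mirror typical clinical region-of-interest scales: mean areas of
#' 745 (small), 14,152 (medium) and 29,337 (large) pixels; each mask's area
#' target is drawn uniformly within +-30% of the regime mean, with shape
#' kinds cycling through `kinds`. The large regime defaults to a 448 x 448
#' frame so the biggest blobs fit; small and medium use 256 x 256.
#'
#' @param n number of masks (>= 1).
#' @param regime `"small"`, `"medium"` or `"large"`.
#' @param seed RNG seed; the battery is reproducible bit-for-bit.
#' @param kinds shape kinds to cycle through (default the three smooth,
#'   star-convex families; dumbbells are a separate stressor).
#' @param size optional `c(H, W)` override.
#' @return a list of `n` mask matrices.
#' @export
generate_battery <- function(n, regime = c("small", "medium", "large"),
                             seed = 1L,
                             kinds = c("ellipse", "superellipse", "fourier_blob"),
                             size = NULL) {
  regime <- match.arg(regime)
  n <- as.integer(n)
  if (n < 1L) abort_bs("n must be >= 1", "usage_error")
  mean_area <- c(small = 745, medium = 14152, large = 29337)[[regime]]
  if (is.null(size)) size <- if (regime == "large") c(448L, 448L) else c(256L, 256L)
  set.seed(seed)
  areas <- mean_area * stats::runif(n, 0.7, 1.3)
  kind_seq <- rep_len(kinds, n)
  seeds <- sample.int(2^30, n)
  lapply(seq_len(n), function(i) {
    generate_mask(shape_spec(kind_seq[i], area = areas[i], size = size,
                             seed = seeds[i]))
  })
}

#' Count boundary crossings of rays cast from the mask centroid
#'
#' Walks rays outward from the foreground centroid at `n_angles` uniform
#' angles, sampling every `step` pixels, and counts inside/outside
#' transitions. A star-convex shape crosses its boundary exactly once per
#' ray; any angle with 3 or more crossings certifies a boundary that is
#' multi-valued in polar form — the case single-ray polar encodings cannot
#' represent.
#'
#' @param mask a logical mask matrix.
#' @param n_angles number of ray directions (default 360).
#' @param step sampling step along each ray in pixels (default 0.25).
#' @param min_run shortest inside/outside run (in samples) counted as a real
#'   region; shorter runs are pixel-staircase flicker along near-tangent rays
#'   and are merged into their neighbours (default 3, i.e. 0.75 px).
#' @return an integer vector of crossing counts, one per angle.
#' @export
ray_crossings <- function(mask, n_angles = 360L, step = 0.25, min_run = 3L) {
  mask <- as_mask(mask)
  if (!any(mask)) abort_bs("mask has no foreground", "degenerate_object_error")
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1] - 1); cx <- mean(idx[, 2] - 1)
  rmax <- sqrt(H^2 + W^2)
  rs <- seq(0, rmax, by = step)
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  vapply(angles, function(a) {
    px <- round(cx + rs * cos(a)); py <- round(cy + rs * sin(a))
    ok <- px >= 0 & px < W & py >= 0 & py < H
    inside <- logical(length(rs))
    inside[ok] <- mask[cbind(py[ok] + 1L, px[ok] + 1L)]
    r <- rle(inside)
    keep <- r$lengths >= min_run
    if (!any(keep)) return(0L)
    sum(rle(r$values[keep])$lengths > 0) - 1L  # transitions between real runs
  }, integer(1))
}
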