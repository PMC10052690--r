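#' Equal-complexity polygon encoding of a contour
#'
#' Selects `k` vertices at index-uniform positions along the traced contour
#' (equivalent to arc-length-uniform for densely traced contours), anchored
#' at the top extreme point for determinism. With `k = 20` the polygon holds
#' the same number of points as the default Bezier shape code, making the two
#' representations directly comparable. Contours shorter than `k` points are
#' resampled first.
#'
#' @param contour a contour matrix (columns x, y).
#' @param k number of polygon vertices (default 20).
#' @return a `k` by 2 matrix of vertices, in traversal order.
#' @export
polygon_encode <- function(contour, k = 20L) {
  contour <- as.matrix(contour)
  k <- as.integer(k)
  if (k < 3L) abort_bs("polygon needs k >= 3", "usage_error")
  if (nrow(contour) < k) contour <- resample_polyline(contour, 4L * k)
  n <- nrow(contour)
  start <- find_extreme_points(contour)$indices[["top"]]
  idx <- ((start - 1L + floor((0:(k - 1L)) * n / k)) %% n) + 1L
  contour[idx, , drop = FALSE]
}

# One noisy trial for each representation; degenerate decodes score 0.
noisy_iou <- function(code, polygon, mask, delta, samples_per_segment) {
  H <- nrow(mask); W <- ncol(mask)
  bez <- tryCatch({
    noisy <- shape_code(code$values + stats::rnorm(length(code$values), 0, delta),
                        degree = code$degree)
    mask_iou(rasterize_contour(decode_code(noisy, samples_per_segment), H, W), mask)
  }, error = function(e) 0)
  poly <- tryCatch({
    noisy <- polygon + stats::rnorm(length(polygon), 0, delta)
    mask_iou(rasterize_contour(noisy, H, W), mask)
  }, error = function(e) 0)
  c(bezier = bez, polygon = poly)
}

#' Noise-sensitivity experiment for one mask
#'
#' Emulates the uncertainty of a coordinate-regressing network: i.i.d.
#' Gaussian offsets N(0, delta^2) are added to all 20 points of the Bezier
#' shape code (extreme and control points alike) and, independently, to the
#' 20 polygon vertices; each perturbed representation is decoded, rasterized
#' and scored by IoU against the clean original mask. Deterministic given
#' `seed`.
#'
#' @param mask a logical mask matrix.
#' @param deltas noise standard deviations in pixels (delta = 0 reproduces
#'   the clean representation fidelity).
#' @param trials repetitions per delta (default 20).
#' @param seed optional RNG seed.
#' @param k polygon vertex count (default 20).
#' @param samples_per_segment decode sampling density (default 72).
#' @param smooth_radius passed to [encode_mask()].
#' @return a list with `summary` (data.frame: delta, representation,
#'   mean_iou, sd_iou) and `raw` (data.frame: delta, representation, trial,
#'   iou).
#' @export
perturb_and_score <- function(mask, deltas, trials = 20L, seed = NULL,
                              k = 20L, samples_per_segment = 72L,
                              smooth_radius = 0) {
  mask <- as_mask(mask)
  if (any(deltas < 0) || trials < 1L) {
    abort_bs("deltas must be >= 0 and trials >= 1", "usage_error")
  }
  if (!is.null(seed)) set.seed(seed)
  code <- encode_mask(mask, smooth_radius = smooth_radius)
  polygon <- polygon_encode(extract_contour(smooth_mask(mask, smooth_radius)), k)
  raw <- do.call(rbind, lapply(deltas, function(d) {
    res <- vapply(seq_len(trials), function(tr)
      noisy_iou(code, polygon, mask, d, samples_per_segment), numeric(2))
    data.frame(delta = d,
               representation = rep(c("bezier", "polygon"), each = trials),
               trial = rep(seq_len(trials), 2),
               iou = c(res["bezier", ], res["polygon", ]))
  }))
  agg <- stats::aggregate(iou ~ delta + representation, raw,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(delta = agg$delta, representation = agg$representation,
                        mean_iou = agg$iou[, "mean"], sd_iou = agg$iou[, "sd"])
  list(summary = summary[order(summary$representation, summary$delta), ],
       raw = raw)
}

#' Noise-sensitivity experiment over a battery of masks
#'
#' Runs [perturb_and_score()] on each mask with per-mask seeds derived from
#' `seed` and pools the per-trial IoUs per delta and representation.
#'
#' @param masks a list of logical mask matrices.
#' @param deltas noise standard deviations in pixels.
#' @param trials repetitions per mask and delta.
#' @param seed RNG seed for the whole experiment.
#' @param ... passed through to [perturb_and_score()].
#' @return a data.frame: delta, representation, mean_iou, sd_iou, n_trials.
#' @export
sensitivity_experiment <- function(masks, deltas, trials = 20L, seed = 1L, ...) {
  raw <- do.call(rbind, lapply(seq_along(masks), function(i) {
    r <- perturb_and_score(masks[[i]], deltas, trials,
                           seed = seed + i * 1009L, ...)$raw
    r$shape <- i
    r
  }))
  agg <- stats::aggregate(iou ~ delta + representation, raw,
                          function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  data.frame(delta = agg$delta, representation = agg$representation,
             mean_iou = agg$iou[, "mean"], sd_iou = agg$iou[, "sd"],
             n_trials = agg$iou[, "n"])
}
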