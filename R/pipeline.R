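#' Encode a directory (or files) of mask PNGs to shape-code JSONs
#'
#' One JSON per mask, named after the input file. Per-file failures are
#' logged as warnings and skipped; the return value reports them.
#'
#' @param inputs a directory containing PNG masks, or a vector of PNG paths.
#' @param out_dir output directory (created if missing).
#' @param degree,smooth_radius passed to [encode_mask()].
#' @return invisibly, a data.frame with `input`, `output`, `ok`, `message`.
#' @export
run_encode <- function(inputs, out_dir, degree = 5L, smooth_radius = 0) {
  files <- if (length(inputs) == 1L && dir.exists(inputs)) {
    list.files(inputs, pattern = "\\.png$", full.names = TRUE)
  } else inputs
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(files, function(f) {
    out <- file.path(out_dir, sub("\\.png$", ".json", basename(f)))
    res <- tryCatch({
      write_shape_code(encode_mask(read_mask(f), degree = degree,
                                   smooth_radius = smooth_radius), out)
      list(ok = TRUE, message = "")
    }, error = function(e) {
      warning(sprintf("encode failed for %s: %s", f, conditionMessage(e)),
              call. = FALSE)
      list(ok = FALSE, message = conditionMessage(e))
    })
    data.frame(input = f, output = out, ok = res$ok, message = res$message)
  })
  invisible(do.call(rbind, rows))
}

#' Decode shape-code JSONs to mask PNGs and contour CSVs
#'
#' Codes are rasterized at `size = c(H, W)`; when `scale` differs from 1 the
#' code coordinates are scaled first (Bezier curves are affine-equivariant,
#' so rescaling is exact).
#'
#' @param inputs a directory of `.json` codes, or a vector of paths.
#' @param out_dir output directory.
#' @param size output `c(H, W)` in pixels.
#' @param scale coordinate scale factor applied to codes (default 1).
#' @param samples_per_segment decode sampling density (default 72).
#' @return invisibly, a data.frame with `input`, `ok`, `message`.
#' @export
run_decode <- function(inputs, out_dir, size, scale = 1,
                       samples_per_segment = 72L) {
  files <- if (length(inputs) == 1L && dir.exists(inputs)) {
    list.files(inputs, pattern = "\\.json$", full.names = TRUE)
  } else inputs
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(files, function(f) {
    res <- tryCatch({
      code <- read_shape_code(f)
      if (scale != 1) code <- scale_code(code, scale)
      contour <- decode_code(code, samples_per_segment)
      stem <- sub("\\.json$", "", basename(f))
      write_mask(rasterize_contour(contour, size[1], size[2]),
                 file.path(out_dir, paste0(stem, ".png")))
      write_contour_csv(contour, file.path(out_dir, paste0(stem, ".csv")))
      list(ok = TRUE, message = "")
    }, error = function(e) {
      warning(sprintf("decode failed for %s: %s", f, conditionMessage(e)),
              call. = FALSE)
      list(ok = FALSE, message = conditionMessage(e))
    })
    data.frame(input = f, ok = res$ok, message = res$message)
  })
  invisible(do.call(rbind, rows))
}

#' Compare two mask PNGs and report metrics as JSON
#'
#' @param pred_path,truth_path PNG mask files of identical dimensions.
#' @param samples_per_segment sampling density for the contours used in the
#'   Hausdorff distance.
#' @return a JSON string: `{"iou": ..., "hausdorff": ..., "mcc": ...,
#'   "fp_rate": ..., "fn_rate": ...}`.
#' @export
run_metrics <- function(pred_path, truth_path, samples_per_segment = 72L) {
  pred <- read_mask(pred_path); truth <- read_mask(truth_path)
  cmp <- mask_confusion(pred, truth)
  hd <- hausdorff_distance(extract_contour(pred), extract_contour(truth))
  jsonlite::toJSON(list(iou = cmp$iou, hausdorff = hd, mcc = cmp$mcc,
                        fp_rate = cmp$fp_rate, fn_rate = cmp$fn_rate),
                   auto_unbox = TRUE, digits = NA)
}

#' Round-trip representation fidelity over a battery of masks
#'
#' encode -> decode -> rasterize -> IoU against the source mask, the
#' fidelity measure used to validate the shape representation itself
#' (independent of any prediction model).
#'
#' @param masks list of logical mask matrices.
#' @param degree,smooth_radius passed to [encode_mask()].
#' @param samples_per_segment decode sampling density.
#' @return a numeric vector of per-mask IoUs.
#' @export
representation_fidelity <- function(masks, degree = 5L, smooth_radius = 0,
                                    samples_per_segment = 72L) {
  vapply(masks, function(m) {
    m <- as_mask(m)
    code <- encode_mask(m, degree = degree, smooth_radius = smooth_radius)
    mask_iou(rasterize_contour(decode_code(code, samples_per_segment),
                               nrow(m), ncol(m)), m)
  }, numeric(1))
}

#' Fit-fidelity sweep over Bezier degrees
#'
#' For each mask and degree: encode at that degree, record the mean
#' least-squares fitting residual (mean distance between arc points and the
#' fitted curve at matched parameters, averaged over the four arcs) and the
#' round-trip mask IoU. The residual is non-increasing in the degree on
#' fixed arcs because odd Bernstein spaces are nested under degree
#' elevation.
#'
#' @param masks list of logical mask matrices.
#' @param degrees degrees to sweep (default 3, 5, 7, 9).
#' @param samples_per_segment decode sampling density.
#' @return a data.frame: degree, mean_residual, mean_iou.
#' @export
degree_sweep <- function(masks, degrees = c(3L, 5L, 7L, 9L),
                         samples_per_segment = 72L) {
  rows <- lapply(degrees, function(d) {
    res <- vapply(masks, function(m) {
      m <- as_mask(m)
      contour <- extract_contour(m)
      arcs <- split_contour(contour)
      resid <- mean(vapply(arcs, function(a) fit_residual(a, d), numeric(1)))
      code <- encode_mask(m, degree = d)
      iou <- mask_iou(rasterize_contour(decode_code(code, samples_per_segment),
                                        nrow(m), ncol(m)), m)
      c(resid, iou)
    }, numeric(2))
    data.frame(degree = d, mean_residual = mean(res[1, ]),
               mean_iou = mean(res[2, ]))
  })
  do.call(rbind, rows)
}

# mean distance between arc points and the fitted curve at matched t
fit_residual <- function(arc, degree) {
  arc <- as.matrix(arc)
  if (nrow(arc) < degree + 1L) arc <- resample_polyline(arc, 2L * (degree + 1L))
  seg <- fit_segment(arc, degree)
  fitted <- evaluate_bernstein(seg, seq(0, 1, length.out = nrow(arc)))
  mean(sqrt(rowSums((fitted - arc)^2)))
}
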