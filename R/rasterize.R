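#' Rasterize a closed contour into a binary mask
#'
#' Even-odd polygon scan-fill over pixel centers: the pixel at matrix cell
#' `[y + 1, x + 1]` (center at integer coordinate (x, y)) is foreground when
#' its center lies inside the polygon under the even-odd rule, or exactly on
#' the contour. Self-intersecting contours therefore fill by parity (a
#' figure-eight fills both lobes). Scanline crossings use the standard
#' half-open `[ymin, ymax)` edge rule; an explicit on-edge pass marks centers
#' lying on the contour itself.
#'
#' @param contour a closed contour matrix (columns x, y); the last point
#'   connects implicitly to the first.
#' @param height,width output mask dimensions in pixels (both > 0).
#' @return a logical `height` by `width` mask matrix.
#' @export
#' @examples
#' sq <- cbind(x = c(10.5, 50.5, 50.5, 10.5), y = c(10.5, 10.5, 50.5, 50.5))
#' sum(rasterize_contour(sq, 64, 64))  # 1600
rasterize_contour <- function(contour, height, width) {
  if (!is.numeric(height) || !is.numeric(width) || height <= 0 || width <= 0) {
    abort_bs("height and width must be positive", "usage_error")
  }
  H <- as.integer(height); W <- as.integer(width)
  P <- as.matrix(contour)
  out <- matrix(FALSE, H, W)
  if (nrow(P) < 3L) return(out)
  x1 <- P[, 1]; y1 <- P[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])

  # --- scanline even-odd fill -------------------------------------------
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  nonh <- which(yhi > ylo)
  if (length(nonh)) {
    r0 <- pmax(ceiling(ylo[nonh]), 0L)
    r1 <- pmin(ceiling(yhi[nonh]) - 1L, H - 1L)   # rows with ylo <= r < yhi
    keep <- which(r1 >= r0)
    if (length(keep)) {
      cnt <- r1[keep] - r0[keep] + 1L
      e <- nonh[keep][rep.int(seq_along(keep), cnt)]
      rows <- unlist(lapply(seq_along(keep), function(i) r0[keep[i]]:r1[keep[i]]),
                     use.names = FALSE)
      xc <- x1[e] + (rows - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
      by_row <- split(xc, rows)
      xs <- 0:(W - 1L)
      for (rn in names(by_row)) {
        r <- as.integer(rn)
        cs <- sort(by_row[[rn]])
        inside <- findInterval(xs - 1e-9, cs) %% 2L == 1L
        out[r + 1L, inside] <- TRUE
      }
    }
  }

  # --- centers exactly on the contour count as foreground ----------------
  tol <- 1e-9
  cx_lo <- ceiling(pmin(x1, x2) - tol); cx_hi <- floor(pmax(x1, x2) + tol)
  cy_lo <- ceiling(ylo - tol);          cy_hi <- floor(yhi + tol)
  cx_lo <- pmax(cx_lo, 0L); cy_lo <- pmax(cy_lo, 0L)
  cx_hi <- pmin(cx_hi, W - 1L); cy_hi <- pmin(cy_hi, H - 1L)
  nx <- cx_hi - cx_lo + 1L; ny <- cy_hi - cy_lo + 1L
  cand <- which(nx > 0L & ny > 0L)
  if (length(cand)) {
    npair <- nx[cand] * ny[cand]
    e <- cand[rep.int(seq_along(cand), npair)]
    k <- sequence(npair) - 1L
    px <- cx_lo[e] + k %% nx[e]
    py <- cy_lo[e] + k %/% nx[e]
    ex <- x2[e] - x1[e]; ey <- y2[e] - y1[e]
    len2 <- ex^2 + ey^2
    wx <- px - x1[e]; wy <- py - y1[e]
    cross <- abs(wx * ey - wy * ex)
    dot <- wx * ex + wy * ey
    on_edge <- ifelse(len2 == 0,
                      wx^2 + wy^2 <= tol^2,
                      cross <= tol * sqrt(len2) & dot >= -tol & dot <= len2 + tol)
    if (any(on_edge)) out[cbind(py[on_edge] + 1L, px[on_edge] + 1L)] <- TRUE
  }
  out
}
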