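test_that("iso-contour of an inset rectangle has the analytic chamfered perimeter", {
  # 10x6-pixel rectangle: the 0.5 iso-level runs 0.5 px outside the pixel
  # centers with each corner chamfered, shortening 2(w+h) by 4*(1 - sqrt(2)/2)
  m <- rect_mask(20, 20, 5, 14, 8, 13)
  ct <- extract_contour(m)
  expected <- 2 * (10 + 6) - 4 * (1 - sqrt(2) / 2)
  expect_equal(perimeter(ct), expected, tolerance = 1e-6)
  expect_equal(range(ct[, "x"]), c(4.5, 14.5))
  expect_equal(range(ct[, "y"]), c(7.5, 13.5))
})

test_that("only the largest connected component is traced", {
  m <- rect_mask(30, 30, 2, 11, 2, 11)          # area 100
  m[20:24 + 1, 20:25 + 1] <- TRUE               # area 30
  ct <- extract_contour(m)
  expect_lt(max(ct[, "x"]), 13)
  expect_lt(max(ct[, "y"]), 13)
})

test_that("full-frame foreground closes via padding and padding is invariant", {
  m <- matrix(TRUE, 12, 15)
  ct <- extract_contour(m)
  expect_equal(range(ct[, "x"]), c(-0.5, 14.5))
  expect_equal(range(ct[, "y"]), c(-0.5, 11.5))
  # adding explicit background padding shifts coordinates by the pad only
  inner <- rect_mask(20, 20, 4, 12, 6, 14)
  padded <- matrix(FALSE, 26, 26); padded[4:23, 4:23] <- inner
  a <- extract_contour(inner)
  b <- extract_contour(padded)
  b[, 1] <- b[, 1] - 3; b[, 2] <- b[, 2] - 3
  expect_equal(hausdorff_brute(a, b), 0)
})

test_that("extreme points follow the corner tie rule on flat sides", {
  # marching squares chamfers the rectangle corners, so the flat top spans
  # x in [10, 29] at y = 11.5, etc.; ties resolve to the corner-adjacent ends
  m <- rect_mask(40, 40, 10, 29, 12, 27)
  ex <- find_extreme_points(extract_contour(m))
  p <- ex$points
  expect_equal(as.numeric(p["top", ]),    c(10, 11.5))   # left end of the top
  expect_equal(as.numeric(p["left", ]),   c(9.5, 27))    # bottom end of the left
  expect_equal(as.numeric(p["bottom", ]), c(29, 27.5))   # right end of the bottom
  expect_equal(as.numeric(p["right", ]),  c(29.5, 12))   # top end of the right
})

test_that("a circle yields the four cardinal extreme points", {
  m <- disk_mask(64, 64, 31, 31, 20)
  ex <- find_extreme_points(extract_contour(m))
  expect_equal(as.numeric(ex$points["top", ]),    c(31, 10.5))
  expect_equal(as.numeric(ex$points["left", ]),   c(10.5, 31))
  expect_equal(as.numeric(ex$points["bottom", ]), c(31, 51.5))
  expect_equal(as.numeric(ex$points["right", ]),  c(51.5, 31))
})

test_that("extreme points are invariant to the contour's starting point", {
  ct <- extract_contour(disk_mask(64, 64, 30, 33, 18))
  ex1 <- find_extreme_points(ct)
  shift <- 17L
  ct2 <- rbind(ct[(shift + 1):nrow(ct), ], ct[1:shift, ])
  ex2 <- find_extreme_points(ct2)
  expect_equal(ex1$points, ex2$points)
})

test_that("splitting at extremes conserves every contour point exactly once", {
  ct <- extract_contour(disk_mask(80, 80, 40, 38, 25))
  ex <- find_extreme_points(ct)
  arcs <- split_contour(ct, ex)
  expect_length(arcs, 4)
  # consecutive arcs share one endpoint
  for (k in 1:4) {
    expect_equal(arcs[[k]][nrow(arcs[[k]]), ], arcs[[(k %% 4) + 1]][1, ])
  }
  expect_equal(sum(vapply(arcs, nrow, numeric(1)) - 1), nrow(ct))
  # concatenation minus shared endpoints reproduces the traversal
  rebuilt <- do.call(rbind, lapply(arcs, function(a) a[-nrow(a), , drop = FALSE]))
  start <- ex$indices[["top"]]
  rotated <- rbind(ct[start:nrow(ct), , drop = FALSE],
                   ct[seq_len(start - 1L), , drop = FALSE])
  expect_equal(rebuilt, rotated, ignore_attr = TRUE)
})

test_that("arcs of a dense circle have near-equal point counts", {
  ct <- extract_contour(disk_mask(200, 200, 99, 99, 80))
  arcs <- split_contour(ct)
  counts <- vapply(arcs, nrow, numeric(1))
  expect_lt(max(counts) - min(counts), 0.1 * mean(counts))
})

test_that("morphological smoothing removes spikes and radius 0 is identity", {
  m <- disk_mask(100, 100, 50, 50, 20)
  expect_identical(smooth_mask(m, 0), m)
  spiked <- m
  spiked[50 + 1, 71:90 + 1] <- TRUE   # 1-px spike off the right edge
  sm <- smooth_mask(spiked, 3)
  expect_false(any(sm[50 + 1, 75:90 + 1]))
  expect_lt(abs(sum(sm) - sum(m)) / sum(m), 0.02)
  expect_error(smooth_mask(rect_mask(30, 30, 10, 11, 10, 11), 5),
               class = "degenerate_object_error")
})

test_that("degenerate inputs raise classed errors", {
  expect_error(extract_contour(matrix(FALSE, 10, 10)),
               class = "degenerate_object_error")
  # collinear "contour": leftmost and bottom ties resolve to the same point
  line <- cbind(x = c(0, 0, 0, 0), y = c(0, 1, 2, 3))
  expect_error(find_extreme_points(line), class = "degenerate_object_error")
})

test_that("contour CSV round trip preserves coordinates", {
  ct <- extract_contour(disk_mask(40, 40, 20, 19, 12))
  f <- withr::local_tempfile(fileext = ".csv")
  write_contour_csv(ct, f)
  expect_equal(read_contour_csv(f), ct, ignore_attr = TRUE, tolerance = 1e-12)
})
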