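test_that("fit_segment recovers a known quintic exactly", {
  set.seed(21)
  for (i in 1:5) {
    seg <- random_segment(5)
    arc <- sample_curve(seg, seq(0, 1, length.out = 50))
    fit <- fit_segment(arc, 5)
    expect_lt(max(abs(fit$control_points - seg$control_points)), 1e-8)
    refit <- evaluate_bernstein(fit, seq(0, 1, length.out = 50))
    expect_lt(max(abs(refit - arc)), 1e-8)  # zero residual up to float
  }
})

test_that("fitting collinear points yields a collinear degenerate curve", {
  arc <- cbind(x = seq(0, 19), y = 2 * seq(0, 19) + 1)
  fit <- fit_segment(arc, 5)
  # all control points on the chord y = 2x + 1
  expect_lt(max(abs(fit$control_points[, 2] -
                    (2 * fit$control_points[, 1] + 1))), 1e-9)
  pts <- evaluate_bernstein(fit, runif(50))
  expect_lt(max(abs(pts[, 2] - (2 * pts[, 1] + 1))), 1e-9)
})

test_that("a quarter circle fits with sub-half-pixel radial error", {
  theta <- seq(0, pi / 2, length.out = 100)
  arc <- cbind(x = 100 * cos(theta), y = 100 * sin(theta))
  fit <- fit_segment(arc, 5)
  dense <- evaluate_bernstein(fit, seq(0, 1, length.out = 2000))
  radial_err <- abs(sqrt(rowSums(dense^2)) - 100)
  expect_lt(max(radial_err), 0.5)
})

test_that("short arcs are densified before fitting instead of failing", {
  arc <- cbind(x = c(0, 1, 2), y = c(0, 1, 0))
  fit <- fit_segment(arc, 5)
  expect_equal(nrow(fit$control_points), 6)
  expect_equal(as.numeric(fit$control_points[1, ]), c(0, 0))
  expect_equal(as.numeric(fit$control_points[6, ]), c(2, 0))
})

test_that("encoding any valid mask yields a 40-value code", {
  masks <- list(rect_mask(64, 64, 15, 50, 20, 45),
                disk_mask(64, 64, 32, 30, 22),
                generate_mask(shape_spec("fourier_blob", area = 8000, seed = 2)))
  for (m in masks) {
    code <- encode_mask(m)
    expect_s3_class(code, "shape_code")
    expect_length(code$values, 40)
  }
})

test_that("an axis-aligned square round-trips at high fidelity", {
  m <- rect_mask(64, 64, 12, 51, 12, 51)
  code <- encode_mask(m)
  dec <- rasterize_contour(decode_code(code), 64, 64)
  expect_gte(mask_iou(dec, m), 0.98)
})

test_that("encoding is equivariant under integer translation", {
  m <- disk_mask(128, 128, 50, 46, 25)
  m2 <- matrix(FALSE, 128, 128)
  m2[(which(m, arr.ind = TRUE) + matrix(c(7, 10), sum(m), 2, byrow = TRUE))] <- TRUE
  c1 <- encode_mask(m); c2 <- encode_mask(m2)
  shift <- rep(c(10, 7), 20)  # (+10, +7) in (x, y)
  expect_lt(max(abs(c2$values - (c1$values + shift))), 1e-6)
})

test_that("decode produces 4*(S-1) points and refines consistently", {
  code <- encode_mask(disk_mask(96, 96, 47, 47, 30))
  d72 <- decode_code(code, 72)
  expect_equal(nrow(d72), 4 * 71)
  d1000 <- decode_code(code, 1000)
  gap <- max(sqrt(rowSums(diff(rbind(d72, d72[1, ]))^2)))
  expect_lt(hausdorff_brute(d72, d1000), gap)
})

test_that("decoding a collapsed code gives an empty raster", {
  code <- shape_code(rep(c(40, 40), 20))
  ct <- decode_code(code, 10)
  expect_true(all(abs(ct[, 1] - 40) < 1e-12))
  # coincident points enclose no pixel centers except the on-curve one
  m <- rasterize_contour(ct, 96, 96)
  expect_lte(sum(m), 1)
})

test_that("codes scale exactly with resolution", {
  m <- disk_mask(64, 64, 32, 32, 20)
  code <- encode_mask(m)
  up <- scale_code(code, 2)
  expect_equal(up$values, code$values * 2)
  dec <- decode_code(up, 200)
  expect_equal(dec, decode_code(code, 200) * 2, ignore_attr = TRUE)
})

test_that("fit residual is non-increasing over nested degrees 3,5,7,9", {
  set.seed(31)
  masks <- generate_battery(3, "medium", seed = 44, kinds = "fourier_blob")
  for (m in masks) {
    arcs <- split_contour(extract_contour(m))
    for (a in arcs) {
      res <- vapply(c(3, 5, 7, 9), function(d) {
        fit <- fit_segment(a, d)
        fitted <- evaluate_bernstein(fit, seq(0, 1, length.out = nrow(a)))
        mean(sqrt(rowSums((fitted - a)^2)))
      }, numeric(1))
      expect_true(all(diff(res) <= 1e-9))
    }
  }
})

test_that("shape-code JSON round trip is lossless and rejects bad input", {
  code <- random_code(seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_shape_code(code, f)
  back <- read_shape_code(f)
  expect_identical(back$values, code$values)
  expect_identical(back$degree, code$degree)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$values <- obj$values[-1]
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_shape_code(bad), class = "codec_error")
  expect_error(shape_code(numeric(39)), class = "codec_error")
})

test_that("rasterization matches brute-force point-in-polygon counts", {
  sq <- cbind(x = c(10.5, 50.5, 50.5, 10.5), y = c(10.5, 10.5, 50.5, 50.5))
  expect_equal(sum(rasterize_contour(sq, 64, 64)), 1600)
  # fully outside the frame
  far <- sq; far[, 1] <- far[, 1] + 500
  expect_equal(sum(rasterize_contour(far, 64, 64)), 0)
  # figure-eight fills both lobes under the even-odd rule
  fig8 <- cbind(x = c(5.2, 25.2, 5.2, 25.2), y = c(5.3, 25.3, 25.3, 5.3))
  got <- rasterize_contour(fig8, 32, 32)
  xs <- rep(0:31, each = 32); ys <- rep(0:31, times = 32)
  oracle <- matrix(pracma::inpolygon(xs, ys, fig8[, 1], fig8[, 2]), 32, 32)
  mismatch <- sum(got != oracle)
  expect_lt(mismatch / length(got), 0.005)  # oracle differs only on boundary
  expect_gt(sum(got & oracle), 100)
  expect_error(rasterize_contour(sq, 0, 64), class = "usage_error")
})

test_that("random quintic shapes re-encode at high IoU", {
  # masks rasterized from valid piecewise-quintic codes are (nearly) inside
  # the representable family, so encode-decode must reproduce them closely
  set.seed(77)
  ious <- replicate(5, {
    m <- generate_mask(shape_spec("fourier_blob", area = 12000,
                                  seed = sample.int(1e6, 1)))
    base <- encode_mask(m)
    truth_mask <- rasterize_contour(decode_code(base, 200), 256, 256)
    code2 <- encode_mask(truth_mask)
    mask_iou(rasterize_contour(decode_code(code2, 200), 256, 256), truth_mask)
  })
  expect_gte(mean(ious), 0.97)
})
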