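test_that("binarize hardens probability maps with the >= convention", {
  expect_equal(binarize(matrix(0.6, 3, 3)), matrix(1L, 3, 3))
  expect_equal(binarize(matrix(0.5, 3, 3)), matrix(1L, 3, 3))  # boundary rule
  gt <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_equal(binarize(gt + 0), gt)  # idempotent on hard inputs
  expect_error(binarize(matrix(0.5, 2, 2), threshold = 0), "between 0 and 1")
  expect_error(binarize(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("contour extraction finds regions in scan order, with holes flagged", {
  m <- matrix(0L, 20, 20)
  m[3:12, 3:12] <- 1L              # 10x10 square
  cs <- extract_contours(m)
  expect_length(cs, 1L)
  v <- cs[[1]]$vertices
  # boundary pixels of the square: 4*10 - 4 of them, all on the rim
  expect_equal(nrow(v), 36L)
  expect_true(all(v[, 1] %in% c(2, 11) | v[, 2] %in% c(2, 11)))
  expect_equal(cs[[1]]$pixel_area, 100L)

  # two disjoint squares: ordering follows the scan
  m2 <- matrix(0L, 20, 20)
  m2[2:4, 10:12] <- 1L   # first encountered (row 2)
  m2[10:15, 2:7] <- 1L
  cs2 <- extract_contours(m2)
  expect_length(cs2, 2L)
  expect_equal(cs2[[1]]$vertices[1, ], c(1L, 9L))   # 0-based (row, col)
  expect_equal(cs2[[2]]$pixel_area, 36L)

  # square with a hole: one outer contour + one interior contour
  m3 <- matrix(0L, 12, 12)
  m3[3:9, 3:9] <- 1L
  m3[5:6, 5:6] <- 0L
  cs3 <- extract_contours(m3)
  expect_length(cs3, 2L)
  expect_false(cs3[[1]]$interior)
  expect_true(cs3[[2]]$interior)
  expect_equal(cs3[[2]]$region, cs3[[1]]$region)
  expect_length(Filter(function(x) !x$interior, cs3), 1L)
  expect_equal(extract_contours(matrix(0L, 5, 5)), list())
})

test_that("component labelling matches an independent flood-fill oracle", {
  set.seed(11)
  for (i in 1:40) {
    m <- matrix(rbinom(20 * 20, 1, 0.25), 20, 20)
    lab <- cc_label8_pkg(m)
    ref <- oracle_label8(m)
    expect_equal(attr(lab, "n"), max(ref))
    # identical partitions (labels assigned in the same scan order)
    expect_equal(as.integer(lab), as.integer(ref))
  }
})

test_that("largest_contour picks the maximal area with scan-order ties", {
  m <- matrix(0L, 30, 30)
  m[2:13, 2:13] <- 1L      # area 144
  m[20:24, 20:24] <- 1L    # area 25
  cs <- extract_contours(m)
  expect_equal(largest_contour(cs)$pixel_area, 144L)
  expect_identical(largest_contour(cs[1]), cs[[1]])  # single contour identity
  # equal areas: tie breaks to first in scan order
  m2 <- matrix(0L, 20, 20)
  m2[2:6, 2:6] <- 1L
  m2[10:14, 10:14] <- 1L
  cs2 <- extract_contours(m2)
  expect_equal(largest_contour(cs2)$region, 1L)
  expect_error(largest_contour(list()), "no segmented region")
})

test_that("analytic square polygon reproduces area, perimeter, CI = pi/4", {
  s <- 17; scale <- 0.01
  sq <- cbind(c(0, 0, s, s), c(0, s, s, 0))
  m <- measure_contour(sq, scale)
  expect_equal(m$area_mm2, (s * scale)^2)
  expect_equal(m$perimeter_mm, 4 * s * scale)
  expect_equal(m$circularity, pi / 4)
  expect_error(measure_contour(sq[1:2, ], scale), "degenerate")
  expect_error(measure_contour(sq, 0), "positive")
})

test_that("a rasterised disc measures close to its analytic values", {
  r <- 50
  m <- disc_mask(121, 61, 61, r)
  meas <- measure_mask(m, 1)
  expect_lt(abs(meas$circularity - 1), 0.1)
  expect_gte(meas$circularity, 0.95)
  expect_lt(abs(meas$area_mm2 - pi * r^2) / (pi * r^2), 0.02)
  expect_lt(abs(meas$perimeter_mm - 2 * pi * r) / (2 * pi * r), 0.03)
})

test_that("scaling mm_per_pixel scales A by k^2, P by k, CI unchanged", {
  f <- sample_faz_mask(synth_config(image_size = c(128, 128),
                                    radius_range = c(20, 30),
                                    center_jitter = 5), seed = 3)
  m1 <- measure_mask(f$mask, 0.01)
  m3 <- measure_mask(f$mask, 0.03)
  expect_equal(m3$area_mm2, 9 * m1$area_mm2, tolerance = 1e-12)
  expect_equal(m3$perimeter_mm, 3 * m1$perimeter_mm, tolerance = 1e-12)
  expect_equal(m3$circularity, m1$circularity, tolerance = 1e-12)
})

test_that("polygon area agrees with pixel-count area for large regions", {
  set.seed(21)
  for (i in 1:10) {
    r <- runif(1, 14, 30)  # pixel areas ~600-2800
    m <- disc_mask(80, runif(1, 35, 45), runif(1, 35, 45), r)
    meas <- measure_mask(m, 1)
    expect_gt(meas$pixel_area, 500)
    expect_lt(abs(meas$area_px - meas$pixel_area) / meas$pixel_area, 0.05)
  }
})

test_that("the pipeline is scale-equivariant under integer resampling", {
  f <- sample_faz_mask(synth_config(image_size = c(96, 96),
                                    radius_range = c(18, 24),
                                    center_jitter = 3), seed = 9)
  k <- 3L
  big <- f$mask[rep(seq_len(96), each = k), rep(seq_len(96), each = k)]
  a1 <- measure_mask(f$mask, 1)$area_px
  a2 <- measure_mask(big, 1)$area_px
  expect_lt(abs(a2 - k^2 * a1) / (k^2 * a1), 0.02)
})

test_that("CI ranks disc above square above star at comparable areas", {
  disc <- disc_mask(101, 51, 51, 30)
  square <- matrix(0L, 101, 101); square[25:77, 25:77] <- 1L
  # five-lobed star r(theta) = r0 (1 + 0.45 cos 5 theta), decisively
  # non-circular even after boundary smoothing
  rows <- matrix(seq_len(101), 101, 101); cols <- t(rows)
  th <- atan2(rows - 51, cols - 51)
  rr <- sqrt((rows - 51)^2 + (cols - 51)^2)
  star <- matrix(as.integer(rr < 27 * (1 + 0.45 * cos(5 * th))), 101, 101)
  ci <- function(m) measure_mask(m, 1)$circularity
  expect_gt(ci(disc), ci(square))
  expect_gt(ci(square), ci(star))
  expect_lte(ci(disc), 1.05)  # CI <= 1 + discretisation allowance
})

test_that("empty predictions yield a flagged no-FAZ result", {
  res <- measure_mask(matrix(0L, 16, 16))
  expect_true(res$no_faz)
  expect_equal(res$n_regions, 0L)
  expect_true(is.na(res$area_mm2))
  tab <- measure_masks(list(a = matrix(0L, 8, 8),
                            b = disc_mask(32, 16, 16, 6)))
  expect_equal(tab$no_faz, c(TRUE, FALSE))
  expect_equal(nrow(tab), 2L)
})
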