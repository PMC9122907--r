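test_that("mask sampling is reproducible and respects its radius bounds", {
  cfg <- synth_config(image_size = c(96, 96), radius_range = c(10, 20),
                      center_jitter = 4)
  a <- sample_faz_mask(cfg, seed = 3)
  b <- sample_faz_mask(cfg, seed = 3)
  expect_identical(a$mask, b$mask)
  expect_identical(a$polygon, b$polygon)
  expect_false(identical(a$mask, sample_faz_mask(cfg, seed = 4)$mask))

  # analytic area bound: pi r^2 (1 +/- sum|a_k|)^2 with r in the config range
  amax <- sum(cfg$roughness / seq_len(cfg$n_harmonics))
  for (s in 1:10) {
    f <- sample_faz_mask(cfg, seed = s)
    expect_gte(f$true_area_px, pi * 10^2 * (1 - amax)^2)
    expect_lte(f$true_area_px, pi * 20^2 * (1 + amax)^2)
    expect_equal(sum(f$mask %in% 0:1), length(f$mask))
    # the ground-truth region is a single 8-connected component
    expect_equal(attr(cc_label8_pkg(f$mask), "n"), 1L)
  }
})

test_that("a zero-roughness sample is a disc with near-unit circularity", {
  cfg <- synth_config(image_size = c(140, 140), radius_range = c(50, 50),
                      roughness = 0, center_jitter = 0)
  f <- sample_faz_mask(cfg, seed = 1)
  m <- measure_mask(f$mask, 1)
  expect_gte(m$circularity, 0.95)
  expect_lte(m$circularity, 1.05)
})

test_that("measured ground-truth area tracks the analytic truth (r0 >= 30)", {
  cfg <- synth_config(radius_range = c(30, 42))  # 320 px field
  for (s in 1:6) {
    f <- sample_faz_mask(cfg, seed = 10 + s)
    m <- measure_mask(f$mask, f$mm_per_pixel)
    expect_lt(abs(m$area_mm2 - f$true_area_mm2) / f$true_area_mm2, 0.03)
  }
})

test_that("vessel rendering is seeded, dark inside the zone, bright outside", {
  cfg <- synth_config(image_size = c(64, 64), radius_range = c(10, 14),
                      center_jitter = 2, vessel_density = 60L)
  f <- sample_faz_mask(cfg, seed = 2)
  v1 <- generate_vessels(f$mask, cfg, seed = 5)
  v2 <- generate_vessels(f$mask, cfg, seed = 5)
  expect_identical(v1, v2)
  # contrast: mean intensity inside the avascular zone below outside
  ratios <- vapply(1:20, function(s) {
    fs <- sample_faz_mask(cfg, seed = 100 + s)
    vs <- generate_vessels(fs$mask, cfg, seed = 200 + s)
    mean(vs[fs$mask == 1]) / mean(vs[fs$mask == 0])
  }, numeric(1))
  expect_true(all(ratios < 1))
  # zero density: background speckle only
  cfg0 <- cfg; cfg0$vessel_density <- 0L
  v0 <- generate_vessels(f$mask, cfg0, seed = 1)
  expect_lt(max(v0), 0.2)
})

test_that("degradation applies the configured artifact levels", {
  cfg <- synth_config(image_size = c(64, 64))
  img <- matrix(0.5, 64, 64)
  # all noise off: identity
  quiet <- cfg
  quiet$salt_pepper <- 0; quiet$scan_lines <- 0L
  quiet$blur_sigma <- 0; quiet$dropout_patches <- 0L
  expect_identical(degrade(img, quiet, seed = 1), img)

  # salt-and-pepper flip fraction ~ Binomial(n, p) on a mid-grey image
  sp <- quiet; sp$salt_pepper <- 0.05
  out <- degrade(img, sp, seed = 2)
  frac <- mean(out != 0.5)
  n <- length(img); p <- 0.05
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))

  # blur reduces total variation
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  noisy <- degrade(matrix(runif(64 * 64), 64, 64), quiet, seed = 1)
  bl <- quiet; bl$blur_sigma <- 1.2
  blurred <- degrade(noisy, bl, seed = 1)
  expect_lt(tv(blurred), tv(noisy))

  # capillary dropout zeroes ellipse patches
  dp <- quiet; dp$dropout_patches <- 2L; dp$dropout_size <- 10
  out2 <- degrade(img, dp, seed = 3)
  expect_gt(sum(out2 == 0), 40)
})

test_that("datasets are reproducible with per-sample seed streams", {
  cfg <- synth_config(image_size = c(48, 48), radius_range = c(7, 11),
                      center_jitter = 2, vessel_density = 20L,
                      dropout_size = 5)
  d1 <- make_dataset(4, cfg, base_seed = 7)
  d2 <- make_dataset(4, cfg, base_seed = 7)
  expect_identical(d1$samples[[3]]$image, d2$samples[[3]]$image)
  expect_identical(d1$manifest, d2$manifest)
  expect_equal(nrow(d1$manifest), 4L)
  expect_equal(dim(d1$samples[[1]]$image), c(48L, 48L, 3L))
  # samples differ from each other
  expect_false(identical(d1$samples[[1]]$gt_mask, d1$samples[[2]]$gt_mask))
  arr <- dataset_arrays(d1)
  expect_equal(dim(arr$x), c(48L, 48L, 3L, 4L))
  expect_equal(dim(arr$y), c(48L, 48L, 4L))
})
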