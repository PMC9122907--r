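#' Synthetic OCTA-like image configuration
#'
#' Parameters of the synthetic en-face angiography generator. The generator
#' emulates the qualitative features of clinical superficial-plexus images
#' that make avascular-zone segmentation hard: an irregular star-convex
#' avascular region shifted away from the image centre, surrounding
#' curvilinear vessel texture, salt-and-pepper noise, horizontal scan-line
#' artifacts, Gaussian blur, and capillary-dropout patches. Mechanics are
#' synthetic stand-ins, but their statistical levers (boundary roughness,
#' noise strength) map onto the image-quality axes seen in practice.
#'
#' Defaults describe a 3 x 3 mm, 320-pixel field: avascular-zone radii of
#' 15-42 px correspond to areas of roughly 0.06-0.5 mm^2, the range observed
#' across normal and glaucomatous eyes.
#'
#' @param image_size height and width in pixels.
#' @param radius_range min/max mean radius of the avascular zone (pixels).
#' @param n_harmonics number of boundary harmonics.
#' @param roughness boundary roughness; harmonic `k` has amplitude about
#'   `roughness/k` relative to the mean radius.
#' @param center_jitter maximum displacement of the zone centre from the
#'   image centre (pixels).
#' @param vessel_density number of vessel random walks per image.
#' @param vessel_rim_fraction fraction of walks seeded on the avascular-zone
#'   rim (the bright perifoveal ring).
#' @param salt_pepper per-pixel probability of an impulse-noise flip.
#' @param scan_lines number of horizontal scan-line artifacts.
#' @param scan_line_strength additive strength of a scan line.
#' @param blur_sigma Gaussian blur width (pixels); 0 disables.
#' @param dropout_patches number of capillary-dropout (zeroed ellipse)
#'   patches.
#' @param dropout_size typical semi-axis of a dropout ellipse (pixels).
#' @param image_width_mm physical scan width.
#' @return A `faz_synth_config` list.
#' @export
synth_config <- function(image_size = c(320L, 320L),
                         radius_range = c(15, 42),
                         n_harmonics = 5L,
                         roughness = 0.12,
                         center_jitter = 15,
                         vessel_density = 300L,
                         vessel_rim_fraction = 0.35,
                         salt_pepper = 0.02,
                         scan_lines = 3L,
                         scan_line_strength = 0.35,
                         blur_sigma = 1.0,
                         dropout_patches = 2L,
                         dropout_size = 18,
                         image_width_mm = 3) {
  stopifnot(radius_range[1] > 0, radius_range[2] >= radius_range[1],
            salt_pepper >= 0, salt_pepper <= 1, roughness >= 0)
  structure(list(image_size = as.integer(rep_len(image_size, 2L)),
                 radius_range = radius_range, n_harmonics = as.integer(n_harmonics),
                 roughness = roughness, center_jitter = center_jitter,
                 vessel_density = as.integer(vessel_density),
                 vessel_rim_fraction = vessel_rim_fraction,
                 salt_pepper = salt_pepper, scan_lines = as.integer(scan_lines),
                 scan_line_strength = scan_line_strength,
                 blur_sigma = blur_sigma,
                 dropout_patches = as.integer(dropout_patches),
                 dropout_size = dropout_size,
                 image_width_mm = image_width_mm),
            class = "faz_synth_config")
}

#' Low-noise ("visually clear") variant of a synthetic configuration
#'
#' Mirrors the visually clear subset of a clinical dataset: minimal impulse
#' noise, no scan lines or dropout, light blur.
#'
#' @param config a [synth_config()].
#' @return The modified configuration.
#' @export
synth_config_clear <- function(config = synth_config()) {
  config$salt_pepper <- 0.004
  config$scan_lines <- 0L
  config$scan_line_strength <- 0
  config$blur_sigma <- min(config$blur_sigma, 0.5)
  config$dropout_patches <- 0L
  config
}

# evaluate and restore the RNG state around `expr`
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample an avascular-zone mask with analytic ground truth
#'
#' Draws a star-convex region \eqn{r(\theta) = r_0 (1 + \sum_k a_k
#' \cos(k\theta + \phi_k))} with random phases, rasterised at a jittered
#' centre, and returns both the pixel mask and the continuous boundary
#' polygon from which analytic ("true") area and perimeter are computed.
#' Draws whose boundary would leave the image are resampled (bounded
#' retries).
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the same seed always yields the same mask.
#' @return A list: `mask` (0/1 matrix), `polygon` (dense n x 2 (row, col)
#'   matrix of the continuous boundary), `center`, `r0`, `amplitudes`,
#'   `phases`, `true_area_px`, `true_perimeter_px`, `true_area_mm2`,
#'   `true_perimeter_mm`, `mm_per_pixel`.
#' @export
sample_faz_mask <- function(config = synth_config(), seed = 1L) {
  with_seed(seed, {
    H <- config$image_size[1]; W <- config$image_size[2]
    K <- config$n_harmonics
    margin <- 3
    for (try in 1:20) {
      r0 <- stats::runif(1, config$radius_range[1], config$radius_range[2])
      amp <- config$roughness * stats::runif(K, 0.3, 1) / seq_len(K)
      phi <- stats::runif(K, 0, 2 * pi)
      cy <- (H + 1) / 2 + stats::runif(1, -1, 1) * config$center_jitter
      cx <- (W + 1) / 2 + stats::runif(1, -1, 1) * config$center_jitter
      rmax <- r0 * (1 + sum(amp))
      if (cy - rmax >= margin && cy + rmax <= H - margin + 1 &&
          cx - rmax >= margin && cx + rmax <= W - margin + 1) break
      if (try == 20) stop("could not place the avascular zone inside the image; ",
                          "reduce `radius_range` or `center_jitter`")
    }
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    dy <- rows - cy; dx <- cols - cx
    theta <- atan2(dy, dx)
    rb <- r0
    for (k in seq_len(K)) rb <- rb + r0 * amp[k] * cos(k * theta + phi[k])
    mask <- matrix(as.integer(sqrt(dy^2 + dx^2) < rb), H, W)

    th <- seq(0, 2 * pi, length.out = 2049L)[-2049L]
    rth <- r0 * (1 + colSums(amp * cos(outer(seq_len(K), th) + phi)))
    poly <- cbind(row = cy + rth * sin(th), col = cx + rth * cos(th))
    a_px <- abs(shoelace(poly))
    j <- c(2:nrow(poly), 1L)
    p_px <- sum(sqrt((poly[j, 1] - poly[, 1])^2 + (poly[j, 2] - poly[, 2])^2))
    mpp <- config$image_width_mm / W
    list(mask = mask, polygon = poly, center = c(cy, cx), r0 = r0,
         amplitudes = amp, phases = phi,
         true_area_px = a_px, true_perimeter_px = p_px,
         true_area_mm2 = a_px * mpp^2, true_perimeter_mm = p_px * mpp,
         mm_per_pixel = mpp)
  })
}

#' Render vessel texture around an avascular zone
#'
#' Draws branching, direction-persistent random walks as bright curvilinear
#' strokes over a low-intensity speckle background. A fraction of walks is
#' seeded on the avascular-zone rim with outward headings (the bright
#' perifoveal ring); strokes never enter the zone, which stays dark.
#'
#' @param mask avascular-zone mask from [sample_faz_mask()].
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return H x W matrix in \[0, 1\].
#' @export
generate_vessels <- function(mask, config = synth_config(), seed = 1L) {
  with_seed(seed, {
    H <- nrow(mask); W <- ncol(mask)
    img <- matrix(0.06 + 0.06 * stats::runif(H * W), H, W)
    n <- config$vessel_density
    if (n == 0) { img[mask == 1] <- img[mask == 1] * 0.5; return(img) }
    rim <- stats::rbinom(n, 1, config$vessel_rim_fraction) == 1
    # rim seeds: just outside the zone boundary, heading outward
    ring <- which(mask == 0 &
                  (rbind(mask[-1, ], 0) | rbind(0, mask[-H, ]) |
                   cbind(mask[, -1], 0) | cbind(0, mask[, -W])) > 0)
    cy <- mean(which(mask == 1, arr.ind = TRUE)[, 1])
    cx <- mean(which(mask == 1, arr.ind = TRUE)[, 2])
    if (length(ring) == 0) rim[] <- FALSE
    for (v in seq_len(n)) {
      if (rim[v]) {
        p <- ring[sample.int(length(ring), 1L)]
        r <- (p - 1L) %% H + 1L; c <- (p - 1L) %/% H + 1L
        dir <- atan2(r - cy, c - cx)
      } else {
        r <- stats::runif(1, 1, H); c <- stats::runif(1, 1, W)
        dir <- stats::runif(1, 0, 2 * pi)
      }
      len <- stats::runif(1, 20, 70)
      bright <- stats::runif(1, 0.45, 1)
      rr <- r; cc <- c
      for (s in seq_len(len)) {
        dir <- dir + stats::rnorm(1, 0, 0.25)
        rr <- rr + sin(dir); cc <- cc + cos(dir)
        ri <- round(rr); ci <- round(cc)
        if (ri < 1 || ri > H || ci < 1 || ci > W) break
        if (mask[ri, ci] == 1) break
        img[ri, ci] <- max(img[ri, ci], bright)
        # faint 4-neighbourhood halo widens the stroke
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          r2 <- ri + d[1]; c2 <- ci + d[2]
          if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W && mask[r2, c2] == 0)
            img[r2, c2] <- max(img[r2, c2], 0.45 * bright)
        }
      }
    }
    img[mask == 1] <- img[mask == 1] * 0.5
    pmin(img, 1)
  })
}

#' Degrade an image with acquisition-like artifacts
#'
#' Applies, in order: capillary-dropout patches (zeroed ellipses),
#' salt-and-pepper impulse noise, horizontal scan lines, and Gaussian blur;
#' the result is clipped to \[0, 1\]. With all noise levels zero the image
#' is returned unchanged.
#'
#' @param image H x W matrix in \[0, 1\].
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return Degraded H x W matrix in \[0, 1\].
#' @export
degrade <- function(image, config = synth_config(), seed = 1L) {
  with_seed(seed, {
    H <- nrow(image); W <- ncol(image)
    img <- image
    if (config$dropout_patches > 0) {
      for (p in seq_len(config$dropout_patches)) {
        pcy <- stats::runif(1, 1, H); pcx <- stats::runif(1, 1, W)
        ay <- stats::runif(1, 0.4, 1) * config$dropout_size
        ax <- stats::runif(1, 0.4, 1) * config$dropout_size
        rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W, byrow = TRUE)
        img[((rows - pcy) / ay)^2 + ((cols - pcx) / ax)^2 <= 1] <- 0
      }
    }
    if (config$salt_pepper > 0) {
      flip <- stats::runif(H * W) < config$salt_pepper
      img[flip] <- stats::rbinom(sum(flip), 1, 0.5)
    }
    if (config$scan_lines > 0) {
      for (s in seq_len(config$scan_lines)) {
        row <- sample.int(H, 1L)
        sign <- if (stats::runif(1) < 0.5) 1 else -1
        band <- row:min(H, row + sample(0:1, 1))
        img[band, ] <- img[band, ] + sign * config$scan_line_strength
      }
    }
    img <- pmin(pmax(img, 0), 1)
    if (config$blur_sigma > 0) img <- gaussian_blur(img, config$blur_sigma)
    pmin(pmax(img, 0), 1)
  })
}

# separable Gaussian blur with edge renormalisation
gaussian_blur <- function(image, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {  # along rows (columns of the matrix move)
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H, W)
    wsum <- matrix(0, H, W)
    for (o in -rad:rad) {
      src <- seq_len(H) + o
      ok <- src >= 1 & src <= H
      out[ok, ] <- out[ok, ] + k[o + rad + 1] * m[src[ok], ]
      wsum[ok, ] <- wsum[ok, ] + k[o + rad + 1]
    }
    out / wsum
  }
  t(blur1(t(blur1(image))))
}

#' Generate one synthetic sample
#'
#' Composes [sample_faz_mask()], [generate_vessels()] and [degrade()] under
#' a single seed and replicates the grayscale image to three channels (the
#' network's input format).
#'
#' @param config a [synth_config()].
#' @param seed integer seed; byte-identical output for equal seeds.
#' @return A list: `image` (H x W x 3 array in \[0,1\]), `gt_mask` (0/1
#'   matrix), `true_area_mm2`, `true_perimeter_mm`, `seed`, `faz` (the full
#'   [sample_faz_mask()] record).
#' @export
synth_sample <- function(config = synth_config(), seed = 1L) {
  faz <- sample_faz_mask(config, seed = seed)
  clean <- generate_vessels(faz$mask, config, seed = seed + 1000003L)
  noisy <- degrade(clean, config, seed = seed + 2000003L)
  image <- array(noisy, c(dim(noisy), 3L))
  list(image = image, gt_mask = faz$mask,
       true_area_mm2 = faz$true_area_mm2,
       true_perimeter_mm = faz$true_perimeter_mm,
       seed = seed, faz = faz)
}

#' Generate a dataset of synthetic samples with a manifest
#'
#' Sample `i` uses seed `base_seed + i`, so datasets are reproducible and
#' individual samples can be regenerated in isolation.
#'
#' @param n number of samples (>= 1).
#' @param config a [synth_config()].
#' @param base_seed integer base seed.
#' @param dir optional directory: when given, images and 0/255 masks are
#'   written as PNG files alongside `manifest.csv`.
#' @return A list with `samples` (list of [synth_sample()] results) and
#'   `manifest` (tibble: id, seed, r0, true area/perimeter, noise settings).
#' @export
make_dataset <- function(n, config = synth_config(), base_seed = 1L,
                         dir = NULL) {
  stopifnot(n >= 1)
  samples <- lapply(seq_len(n), function(i) synth_sample(config, base_seed + i))
  manifest <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    s <- samples[[i]]
    tibble::tibble(id = sprintf("sample_%04d", i), seed = s$seed,
                   r0_px = s$faz$r0,
                   true_area_mm2 = s$true_area_mm2,
                   true_perimeter_mm = s$true_perimeter_mm,
                   salt_pepper = config$salt_pepper,
                   scan_lines = config$scan_lines,
                   blur_sigma = config$blur_sigma,
                   dropout_patches = config$dropout_patches)
  }))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_image(samples[[i]]$image,
                  file.path(dir, sprintf("sample_%04d.png", i)))
      write_mask(samples[[i]]$gt_mask,
                 file.path(dir, sprintf("sample_%04d_mask.png", i)))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Stack dataset samples into training arrays
#'
#' @param samples list of [synth_sample()] results (or a [make_dataset()]
#'   result).
#' @return List with `x` (H x W x 3 x N images) and `y` (H x W x N masks).
#' @export
dataset_arrays <- function(samples) {
  if (!is.null(samples$samples)) samples <- samples$samples
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d, n))
  y <- array(0L, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    y[, , i] <- samples[[i]]$gt_mask
  }
  list(x = x, y = y)
}
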