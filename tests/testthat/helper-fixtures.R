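# shared fixtures and independent oracles (kept free of the package's own
# geometry/metric code paths wherever they serve as cross-checks)

tiny_arch <- function(size = 32L, width = 8L, mid = NULL, dropout = 0) {
  arch_config(input_size = c(size, size), width_policy = "fixed",
              base_width = width, skip_mode = "add", up_mode = "upsample",
              midblock_min_channels = mid, dropout_rate = dropout)
}

# small, easy segmentation task: dark disc on bright vessel-free noise
tiny_dataset <- function(n, size = 32L, seed = 1L) {
  cfg <- synth_config(image_size = c(size, size), radius_range = c(5, 9),
                      center_jitter = 2, vessel_density = 12L,
                      dropout_patches = 0L, scan_lines = 0L,
                      salt_pepper = 0.003, blur_sigma = 0.4)
  make_dataset(n, cfg, base_seed = seed)
}

# brute-force set-operation metrics on index sets (independent oracle)
oracle_jaccard <- function(gt, pred) {
  A <- which(gt == 1); B <- which(pred == 1)
  u <- length(union(A, B))
  if (u == 0) 1 else length(intersect(A, B)) / u
}
oracle_dice <- function(gt, pred) {
  A <- which(gt == 1); B <- which(pred == 1)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# independent flood-fill labelling (R implementation, 8-connected)
oracle_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] != 0 && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

disc_mask <- function(size, cy, cx, r) {
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  matrix(as.integer(sqrt((rows - cy)^2 + (cols - cx)^2) < r), size, size)
}

# random multi-disc mask with distinct radii (unambiguous largest region)
random_disc_mask <- function(size = 28L, n_blobs = 2L) {
  radii <- sort(sample(seq(2L, 6L), n_blobs)) + seq(0, (n_blobs - 1)) * 0.5
  m <- matrix(0L, size, size)
  centres <- list()
  for (r in rev(radii)) {  # place large first
    for (try in 1:50) {
      cy <- runif(1, r + 1.5, size - r - 0.5)
      cx <- runif(1, r + 1.5, size - r - 0.5)
      ok <- all(vapply(centres, function(p)
        sqrt((p[1] - cy)^2 + (p[2] - cx)^2) > p[3] + r + 2.5, logical(1)))
      if (ok) break
    }
    if (!ok) return(NULL)
    centres[[length(centres) + 1L]] <- c(cy, cx, r)
    m <- pmax(m, disc_mask(size, cy, cx, r))
  }
  list(mask = m, centres = centres)
}

# package-internal labelling, wrapped for tests
cc_label8_pkg <- function(mask) {
  fazseg:::cc_label8(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}
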