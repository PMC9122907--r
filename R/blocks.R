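#' @title Building blocks (reference implementations)
#' @description Plain-R implementations of the network's building blocks.
#'   These are the readable reference for the semantics of the C++ training
#'   engine and are cross-checked against it in the test suite; they operate
#'   on single H x W x C arrays in double precision.
#' @name blocks
NULL

# 3x3 (or 1x1) same-padding convolution of an H x W x C array.
# kernel: k x k x Cin x Cout array; bias: length-Cout vector.
conv2d_same <- function(x, kernel, bias = NULL) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  k <- dim(kernel)[1]
  cin <- dim(kernel)[3]
  cout <- dim(kernel)[4]
  stopifnot(dim(x)[3] == cin)
  H <- dim(x)[1]; W <- dim(x)[2]
  pad <- (k - 1L) %/% 2L
  out <- array(0, c(H, W, cout))
  xp <- array(0, c(H + 2L * pad, W + 2L * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    patch <- xp[(dy - 1L) + seq_len(H), (dx - 1L) + seq_len(W), , drop = FALSE]
    pm <- matrix(patch, H * W, cin)
    wm <- matrix(kernel[dy, dx, , ], cin, cout)
    out <- out + array(pm %*% wm, c(H, W, cout))
  }
  if (!is.null(bias)) out <- out + rep(bias, each = H * W)
  out
}

#' Convolutional block: 3x3 convolution, batch normalisation, ReLU
#'
#' One convolution block of the architecture: a 3x3 same-padding convolution
#' with bias, channel-wise normalisation, and rectification. Weights default
#' to He-normal kernels with identity normalisation, so the block can be
#' used standalone; pass explicit `weights` to reproduce a specific layer.
#'
#' @param x H x W x C input array (a 2-d matrix is treated as one channel).
#' @param filters number of output channels (>= 1).
#' @param weights optional list with elements `kernel` (3 x 3 x C x filters),
#'   `bias`, `gamma`, `beta`, `mean`, `var`; missing elements default to
#'   He-normal kernel, zero bias and identity normalisation.
#' @param batchnorm apply the normalisation step.
#' @param activation apply the ReLU.
#' @param eps normalisation stabiliser.
#' @return H x W x filters array; all values are non-negative when
#'   `activation = TRUE`.
#' @export
conv_block <- function(x, filters, weights = NULL, batchnorm = TRUE,
                       activation = TRUE, eps = 1e-3) {
  filters <- as.integer(filters)
  if (filters < 1L) stop("`filters` must be >= 1")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  cin <- dim(x)[3]
  if (is.null(weights)) weights <- list()
  if (is.null(weights$kernel))
    weights$kernel <- array(stats::rnorm(9 * cin * filters, sd = sqrt(2 / (9 * cin))),
                            c(3, 3, cin, filters))
  if (is.null(weights$bias)) weights$bias <- numeric(filters)
  y <- conv2d_same(x, weights$kernel, weights$bias)
  if (batchnorm) {
    gamma <- weights$gamma %||% rep(1, filters)
    beta <- weights$beta %||% numeric(filters)
    mu <- weights$mean %||% numeric(filters)
    v <- weights$var %||% rep(1, filters)
    H <- dim(y)[1]; W <- dim(y)[2]
    for (c in seq_len(filters))
      y[, , c] <- (y[, , c] - mu[c]) / sqrt(v[c] + eps) * gamma[c] + beta[c]
  }
  if (activation) y[y < 0] <- 0
  y
}

#' Bounded channel-attention block
#'
#' Modified squeeze-and-excitation attention: global average pooling over
#' space, one fully connected C -> C layer with bias, then ReLU followed by
#' a logistic squashing. Because the logistic is applied to a rectified
#' value, every channel weight lies in \[0.5, 1): the least useful channels
#' are halved rather than eliminated, so later layers can still recover
#' them.
#'
#' @param x H x W x C input array.
#' @param kernel optional C x C dense matrix (rows index output units);
#'   defaults to He-normal.
#' @param bias optional length-C bias.
#' @return The input scaled per channel; the channel weights are attached as
#'   attribute `"weights"`.
#' @examples
#' x <- array(runif(8 * 8 * 4), c(8, 8, 4))
#' w <- attr(attention_block(x), "weights")
#' all(w >= 0.5 & w < 1)
#' @export
attention_block <- function(x, kernel = NULL, bias = NULL) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  C <- dim(x)[3]
  if (is.null(kernel)) kernel <- matrix(stats::rnorm(C * C, sd = sqrt(2 / C)), C, C)
  if (is.null(bias)) bias <- numeric(C)
  stopifnot(nrow(kernel) == C, ncol(kernel) == C, length(bias) == C)
  s <- apply(x, 3, mean)
  z <- as.numeric(kernel %*% s + bias)
  w <- stats::plogis(pmax(z, 0))
  out <- x
  for (c in seq_len(C)) out[, , c] <- out[, , c] * w[c]
  structure(out, weights = w)
}

#' Channel-narrowing midblock
#'
#' The bottleneck module of the lightweight network: a convolution at the
#' bottleneck width, successive convolutions halving the channel count down
#' to `min_channels` (each followed by an attention block), a restoring
#' convolution back to the bottleneck width, an additive skip connection
#' from the midblock input, and a final attention block. Only the features
#' needed to reconstruct the segmentation survive the narrow waist.
#' Midblock convolutions are plain conv + ReLU (no batch normalisation).
#'
#' @param x H x W x W0 input array at the bottleneck width W0.
#' @param min_channels narrowest width; a power of two `<=` W0 dividing W0.
#' @param weights optional named list of per-stage weights (elements
#'   `entry`, `narrow1`..., `att1`..., `restore`, `att_out`, each as in
#'   [conv_block()]/[attention_block()]); defaults are random.
#' @return H x W x W0 array (spatial dimensions unchanged).
#' @export
narrowing_midblock <- function(x, min_channels, weights = NULL) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  W0 <- dim(x)[3]
  min_channels <- as.integer(min_channels)
  if (min_channels > W0) stop("`min_channels` (", min_channels,
                              ") exceeds the bottleneck width (", W0, ")")
  if (bitwAnd(min_channels, min_channels - 1L) != 0L)
    stop("`min_channels` must be a power of two")
  weights <- weights %||% list()
  h <- conv_block(x, W0, weights$entry, batchnorm = FALSE)
  widths <- integer(0)
  w <- W0
  while (w > min_channels) { w <- w %/% 2L; widths <- c(widths, w) }
  for (i in seq_along(widths)) {
    h <- conv_block(h, widths[i], weights[[paste0("narrow", i)]], batchnorm = FALSE)
    aw <- weights[[paste0("att", i)]] %||% list(kernel = NULL, bias = NULL)
    h <- attention_block(h, aw$kernel, aw$bias)
  }
  h <- conv_block(h, W0, weights$restore, batchnorm = FALSE)
  h <- h + x  # skip connection from the midblock input
  ao <- weights$att_out %||% list(kernel = NULL, bias = NULL)
  out <- attention_block(h, ao$kernel, ao$bias)
  attr(out, "widths") <- widths
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Full reference forward pass (inference mode), mirroring the C++ engine's
# graph and weight ordering.  Used as the independent cross-check of the
# engine in the test suite; O(slow) but simple.
reference_forward <- function(config, weights, x) {
  w <- arch_widths(config)
  eng <- as_engine_config(config)
  wi <- 0L
  nxt <- function() { wi <<- wi + 1L; weights[[wi]] }
  conv_w <- function(cin, cout, k = 3L, bn = TRUE) {
    kern <- array(nxt(), c(cin, k * k, cout))  # engine rows: (q*cin + ci)
    kern <- aperm(kern, c(2, 1, 3))            # q, ci, cout
    kernel <- array(0, c(k, k, cin, cout))
    for (dy in seq_len(k)) for (dx in seq_len(k))
      kernel[dy, dx, , ] <- kern[(dy - 1L) * k + dx, , ]
    bias <- nxt()
    out <- list(kernel = kernel, bias = bias)
    if (bn) {
      gb <- nxt(); mv <- nxt()
      out$gamma <- gb[seq_len(cout)]; out$beta <- gb[cout + seq_len(cout)]
      out$mean <- mv[seq_len(cout)]; out$var <- mv[cout + seq_len(cout)]
    }
    out
  }
  att_w <- function(C) {
    kernel <- matrix(nxt(), C, C)
    list(kernel = kernel, bias = nxt())
  }
  maxpool2 <- function(a) {
    H <- dim(a)[1] %/% 2L; W <- dim(a)[2] %/% 2L; C <- dim(a)[3]
    out <- array(0, c(H, W, C))
    for (c in seq_len(C)) {
      m <- a[, , c]
      out[, , c] <- pmax(m[seq(1, 2 * H, 2), seq(1, 2 * W, 2)],
                         m[seq(2, 2 * H, 2), seq(1, 2 * W, 2)],
                         m[seq(1, 2 * H, 2), seq(2, 2 * W, 2)],
                         m[seq(2, 2 * H, 2), seq(2, 2 * W, 2)])
    }
    out
  }
  upnearest2 <- function(a) {
    H <- dim(a)[1]; W <- dim(a)[2]; C <- dim(a)[3]
    a[rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), , drop = FALSE]
  }
  conv_transpose <- function(a, cin, cout) {
    kern <- array(nxt(), c(cin, 9L, cout))
    bias <- nxt()
    H <- dim(a)[1]; W <- dim(a)[2]
    out <- array(0, c(2L * H, 2L * W, cout))
    for (dy in 0:2) for (dx in 0:2) {
      wm <- matrix(kern[, dy * 3L + dx + 1L, ], cin, cout)
      contrib <- array(matrix(a, H * W, cin) %*% wm, c(H, W, cout))
      oi <- 2L * seq_len(H) - 2L + dy  # 2i + dy - 1 in 1-based terms
      oj <- 2L * seq_len(W) - 2L + dx
      ok_i <- oi >= 1L & oi <= 2L * H
      ok_j <- oj >= 1L & oj <= 2L * W
      out[oi[ok_i], oj[ok_j], ] <- out[oi[ok_i], oj[ok_j], , drop = FALSE] +
        contrib[ok_i, ok_j, , drop = FALSE]
    }
    out + rep(bias, each = 4L * H * W)
  }
  apply_att <- function(a, C) {
    aw <- att_w(C)
    attention_block(a, aw$kernel, aw$bias)
  }

  h <- x
  if (length(dim(h)) == 2L) dim(h) <- c(dim(h), 1L)
  skips <- list()
  cin <- config$input_channels
  for (i in seq_len(config$depth)) {
    h <- conv_block(h, w$encoder[i], conv_w(cin, w$encoder[i]))
    h <- conv_block(h, w$encoder[i], conv_w(w$encoder[i], w$encoder[i]))
    if (config$attention) h <- apply_att(h, w$encoder[i])
    skips[[i]] <- h
    h <- maxpool2(h)
    cin <- w$encoder[i]
  }
  h <- conv_block(h, w$bottleneck, conv_w(cin, w$bottleneck))
  h <- conv_block(h, w$bottleneck, conv_w(w$bottleneck, w$bottleneck))
  if (config$attention && config$bottleneck_attention)
    h <- apply_att(h, w$bottleneck)
  if (length(w$midblock) > 0) {
    mid_in <- h
    h <- conv_block(h, w$bottleneck, conv_w(w$bottleneck, w$bottleneck, bn = FALSE),
                    batchnorm = FALSE)
    prev <- w$bottleneck
    for (mw in w$midblock) {
      h <- conv_block(h, mw, conv_w(prev, mw, bn = FALSE), batchnorm = FALSE)
      h <- apply_att(h, mw)
      prev <- mw
    }
    h <- conv_block(h, w$bottleneck, conv_w(prev, w$bottleneck, bn = FALSE),
                    batchnorm = FALSE)
    h <- h + mid_in
    h <- apply_att(h, w$bottleneck)
  }
  cur <- w$bottleneck
  for (j in seq_len(config$depth)) {
    skip <- skips[[config$depth + 1L - j]]
    if (config$up_mode == "transpose") {
      h <- conv_transpose(h, cur, w$mirror[j])
      cur <- w$mirror[j]
    } else {
      h <- upnearest2(h)
    }
    if (config$skip_mode == "add") {
      h <- h + skip
    } else {
      h2 <- array(0, c(dim(h)[1], dim(h)[2], cur + dim(skip)[3]))
      h2[, , seq_len(cur)] <- h
      h2[, , cur + seq_len(dim(skip)[3])] <- skip
      h <- h2
      cur <- cur + dim(skip)[3]
    }
    h <- conv_block(h, w$decoder[j], conv_w(cur, w$decoder[j]))
    h <- conv_block(h, w$decoder[j], conv_w(w$decoder[j], w$decoder[j]))
    if (config$attention) h <- apply_att(h, w$decoder[j])
    cur <- w$decoder[j]
  }
  hw <- conv_w(cur, config$output_channels, bn = FALSE)
  h <- conv_block(h, config$output_channels, hw, batchnorm = FALSE,
                  activation = FALSE)
  stats::plogis(h)
}
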