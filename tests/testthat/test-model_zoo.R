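test_that("configuration invariants are enforced", {
  expect_error(arch_config(base_width = 48), "power of two")
  expect_error(arch_config(input_size = c(100, 100)), "divisible")
  expect_error(arch_config(width_policy = "fixed", base_width = 128,
                           attention = FALSE, midblock_min_channels = 16),
               "attention")
  expect_error(arch_config(midblock_min_channels = 48), "power of two")
  expect_error(arch_config(dropout_rate = 1), "dropout_rate")
  expect_error(build_model("NoSuchNet"), "valid presets")
})

test_that("channel plans follow the family's width rules", {
  w <- fazseg:::arch_widths(arch_presets()$Unet_AB)
  expect_equal(w$encoder, c(64, 128, 256, 512))
  expect_equal(w$bottleneck, 1024)
  expect_equal(w$decoder, c(256, 128, 64, 64))
  wa <- fazseg:::arch_widths(arch_presets()$Unet_AB_Upsampling_Add)
  expect_equal(wa$bottleneck, 512)  # add-skips keep the bottleneck at 512
  wl <- fazseg:::arch_widths(arch_presets()$LWBNA_Unet)
  expect_equal(wl$midblock, c(64, 32, 16))
  w8 <- fazseg:::arch_widths(arch_config(width_policy = "fixed", base_width = 128,
                                skip_mode = "add", up_mode = "upsample",
                                midblock_min_channels = 8))
  expect_equal(w8$midblock, c(64, 32, 16, 8))
})

test_that("parameter count is invariant to the input spatial size", {
  n64 <- count_parameters(build_model("LWBNA_Unet", input_size = c(64, 64)))
  n320 <- count_parameters(build_model("LWBNA_Unet", input_size = c(320, 320)))
  expect_identical(n64, n320)
  m1 <- count_parameters(build_model("Unet_AB_64_Upsampling_Add",
                                     input_size = c(32, 32)))
  m2 <- count_parameters(build_model("Unet_AB_64_Upsampling_Add",
                                     input_size = c(96, 96)))
  expect_identical(m1, m2)
})

test_that("conv block semantics: zero weights, shape, rectification", {
  x <- array(runif(8 * 8), c(8, 8, 1))
  zero <- list(kernel = array(0, c(3, 3, 1, 1)), bias = 0)
  expect_equal(conv_block(x, 1, zero, batchnorm = FALSE),
               array(0, c(8, 8, 1)))
  y <- conv_block(array(runif(16 * 16 * 4), c(16, 16, 4)), 6)
  expect_equal(dim(y), c(16, 16, 6))   # same padding preserves spatial dims
  expect_true(all(y >= 0))             # rectified
  expect_error(conv_block(x, 0), ">= 1")
})

test_that("attention weights are bounded in [0.5, 1) and symmetric", {
  x <- array(runif(6 * 6 * 4), c(6, 6, 4))
  # zero dense layer: every weight is logistic(0) = 0.5, output x/2
  y0 <- attention_block(x, kernel = matrix(0, 4, 4), bias = rep(0, 4))
  expect_equal(attr(y0, "weights"), rep(0.5, 4))
  expect_equal(as.numeric(y0), as.numeric(x / 2))
  # random trials stay inside the bound
  set.seed(7)
  for (i in 1:50) {
    C <- sample(2:8, 1)
    xi <- array(rnorm(25 * C), c(5, 5, C))
    w <- attr(attention_block(xi), "weights")
    expect_true(all(w >= 0.5 & w < 1))
  }
  # permuting channels together with the dense layer permutes the weights
  set.seed(8)
  C <- 5
  xi <- array(rnorm(16 * C), c(4, 4, C))
  k <- matrix(rnorm(C * C), C, C); b <- rnorm(C)
  p <- sample(C)
  w1 <- attr(attention_block(xi, k, b), "weights")
  w2 <- attr(attention_block(xi[, , p, drop = FALSE], k[p, p], b[p]), "weights")
  expect_equal(w2, w1[p])
})

test_that("the narrowing midblock halves channels down to the minimum", {
  x <- array(runif(4 * 4 * 16), c(4, 4, 16))
  y <- narrowing_midblock(x, 4)
  expect_equal(attr(y, "widths"), c(8, 4))
  expect_equal(dim(y), dim(x))       # no pooling inside the midblock
  y2 <- narrowing_midblock(x, 2)
  expect_equal(attr(y2, "widths"), c(8, 4, 2))  # one extra halving stage
  expect_error(narrowing_midblock(x, 32), "exceeds")
})

test_that("the C++ engine matches the plain-R reference forward pass", {
  set.seed(5)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (arch in list(
    tiny_arch(32, 8, mid = 2),
    arch_config(input_size = c(32, 32), width_policy = "doubling",
                base_width = 4, skip_mode = "concatenate",
                up_mode = "transpose", dropout_rate = 0))) {
    m <- build_model(arch, seed = 11)
    p_engine <- fazseg:::nn_forward(m$ptr, array(x, c(32, 32, 3, 1)), FALSE)
    p_ref <- fazseg:::reference_forward(arch, fazseg:::model_weights(m), x)
    expect_lt(max(abs(p_engine[, , , 1] - p_ref)), 1e-5)
  }
})

test_that("analytic gradients agree with finite differences", {
  # (a) full-parameter direction on a transpose/concat network.  The FD
  # probe sits on ReLU/max-pool kinks, so agreement is approximate; the
  # tolerance reflects the kink density at this size, and the check is
  # fully deterministic under the fixed seeds.
  arch <- arch_config(input_size = c(8, 8), width_policy = "doubling",
                      base_width = 4, depth = 2, skip_mode = "concatenate",
                      up_mode = "transpose", dropout_rate = 0)
  m <- build_model(arch, seed = 11)
  set.seed(7)
  x <- array(runif(8 * 8 * 3 * 3), c(8, 8, 3, 3))
  y <- array(rbinom(8 * 8 * 3 * 3, 1, 0.4), c(8, 8, 3, 3))
  w <- fazseg:::nn_get_weights(m$ptr)
  loss_at <- function(ww) {
    fazseg:::nn_set_weights(m$ptr, ww)
    fazseg:::nn_train_batch(m$ptr, x, y, "dice", 0, .9, .99, 1e-7)$loss
  }
  invisible(fazseg:::nn_train_batch(m$ptr, x, y, "dice", 0, .9, .99, 1e-7))
  g <- fazseg:::nn_get_grads(m$ptr)
  d <- lapply(seq_along(w), function(i)
    if (grepl("stats", names(w)[i])) 0 * w[[i]] else rnorm(length(w[[i]])))
  ana <- sum(mapply(function(gi, di) sum(gi * di), g, d))
  h <- 3e-5
  num <- (loss_at(mapply(function(a, b) a + h * b, w, d, SIMPLIFY = FALSE)) -
          loss_at(mapply(function(a, b) a - h * b, w, d, SIMPLIFY = FALSE))) /
         (2 * h)
  expect_lt(abs(num - ana), 0.08 * max(abs(num), abs(ana)) + 1e-3)

  # (b) head-only direction on the midblock network: the loss is smooth in
  # the head parameters, so FD agreement is essentially exact
  arch2 <- tiny_arch(16, 4, mid = 2)
  arch2$dropout_rate <- 0
  m2 <- build_model(arch2, seed = 2)
  set.seed(3)
  x2 <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y2 <- array(rbinom(16 * 16 * 3 * 2, 1, 0.3), c(16, 16, 3, 2))
  w2 <- fazseg:::nn_get_weights(m2$ptr)
  loss_at2 <- function(ww) {
    fazseg:::nn_set_weights(m2$ptr, ww)
    fazseg:::nn_train_batch(m2$ptr, x2, y2, "dice", 0, .9, .99, 1e-7)$loss
  }
  invisible(fazseg:::nn_train_batch(m2$ptr, x2, y2, "dice", 0, .9, .99, 1e-7))
  g2 <- fazseg:::nn_get_grads(m2$ptr)
  d2 <- lapply(seq_along(w2), function(i)
    if (grepl("head", names(w2)[i])) rnorm(length(w2[[i]])) else 0 * w2[[i]])
  ana2 <- sum(mapply(function(gi, di) sum(gi * di), g2, d2))
  h2 <- 1e-4
  num2 <- (loss_at2(mapply(function(a, b) a + h2 * b, w2, d2, SIMPLIFY = FALSE)) -
           loss_at2(mapply(function(a, b) a - h2 * b, w2, d2, SIMPLIFY = FALSE))) /
          (2 * h2)
  expect_lt(abs(num2 - ana2), 0.005 * max(abs(num2), abs(ana2)) + 1e-5)
})

test_that("prediction is deterministic, bounded, and order-preserving", {
  m <- build_model(tiny_arch(16, 4), seed = 9)
  set.seed(10)
  a <- array(runif(16 * 16 * 3), c(16, 16, 3))
  b <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p <- predict(m, list(a, b, a))
  expect_true(all(p > 0 & p < 1))          # logistic output range
  expect_equal(p[, , 1], p[, , 3])         # duplicated input, identical maps
  expect_identical(predict(m, a), predict(m, a))  # repeated calls bit-equal
  expect_error(predict(m, array(0.5, c(8, 8, 3))), "16x16x3")
})
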