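test_that("jaccard and dice reproduce hand-counted examples", {
  gt <- matrix(0, 3, 3); gt[c(1, 2, 4, 5)] <- 1      # |GT| = 4
  pred <- matrix(0, 3, 3); pred[c(1, 2, 9)] <- 1     # |P| = 3, overlap 2
  expect_equal(jaccard(gt, pred), 2 / 5)
  expect_equal(dice(gt, pred), 4 / 7)

  same <- matrix(rbinom(25, 1, 0.5), 5, 5)
  same[1] <- 1
  expect_equal(jaccard(same, same), 1)
  expect_equal(dice(same, same), 1)

  a <- matrix(0, 4, 4); a[1:2] <- 1
  b <- matrix(0, 4, 4); b[15:16] <- 1
  expect_equal(jaccard(a, b), 0)
  expect_equal(dice(a, b), 0)
})

test_that("degenerate mask conventions: both empty -> 1, one empty -> 0", {
  z <- matrix(0, 3, 3)
  o <- matrix(0, 3, 3); o[5] <- 1
  expect_equal(dice(z, z), 1)
  expect_equal(jaccard(z, z), 1)
  expect_equal(dice(z, o), 0)
  expect_equal(jaccard(o, z), 0)
})

test_that("metrics validate their inputs", {
  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")
  expect_error(jaccard(matrix(0.5, 2, 2), matrix(0, 2, 2)), "0/1")
})

test_that("D = 2J/(1+J), symmetry and brute-force agreement on random masks", {
  set.seed(42)
  for (i in 1:400) {
    gt <- matrix(rbinom(36, 1, runif(1, 0.1, 0.9)), 6, 6)
    pr <- matrix(rbinom(36, 1, runif(1, 0.1, 0.9)), 6, 6)
    J <- jaccard(gt, pr); D <- dice(gt, pr)
    expect_equal(D, 2 * J / (1 + J))
    expect_equal(J, oracle_jaccard(gt, pr))
    expect_equal(D, oracle_dice(gt, pr))
    expect_equal(D, dice(pr, gt))
    expect_equal(J, jaccard(pr, gt))
  }
})

test_that("growing the overlap at fixed mask sizes never decreases D", {
  # |GT| = |P| = 6 on 16 pixels; move P pixels onto GT one at a time
  gt <- matrix(0, 4, 4); gt[1:6] <- 1
  d_prev <- -1
  for (overlap in 0:6) {
    pred <- matrix(0, 4, 4)
    if (overlap > 0) pred[seq_len(overlap)] <- 1
    if (overlap < 6) pred[16 - seq_len(6 - overlap) + 1] <- 1
    d <- dice(gt, pred)
    expect_gte(d, d_prev)
    d_prev <- d
  }
})

test_that("soft dice loss has the expected closed forms and limits", {
  gt <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_lt(soft_dice_loss(gt, gt), 1e-6)
  expect_gt(soft_dice_loss(gt, 1 - gt), 1 - 1e-5)
  # uniform 0.5 probability: loss = 1 - 2(0.5 k)/(k + 0.5 n)
  k <- sum(gt); n <- length(gt)
  expect_equal(soft_dice_loss(gt, matrix(0.5, 8, 8)),
               1 - (2 * 0.5 * k) / (k + 0.5 * n), tolerance = 1e-5)
  # hard prediction: equals 1 - dice within smoothing tolerance
  pr <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(soft_dice_loss(gt, pr), 1 - dice(gt, pr), tolerance = 1e-5)
  expect_error(soft_dice_loss(gt, matrix(1.5, 8, 8)), "\\[0, 1\\]")
})

test_that("metric_summary gives mean and sample sd with n = 1 handled", {
  expect_equal(metric_summary(c(1, 1, 1))$sd, 0)
  s <- metric_summary(c(0, 1))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, sqrt(0.5), tolerance = 1e-12)
  expect_warning(s1 <- metric_summary(0.9), "single value")
  expect_equal(s1$mean, 0.9)
  expect_equal(s1$sd, 0)
  expect_error(metric_summary(numeric(0)), "non-empty")
})
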