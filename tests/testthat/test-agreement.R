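test_that("Bland-Altman reproduces hand-computed statistics", {
  a <- c(1.1, 0.9, 1.3); b <- a - c(0.1, -0.1, 0.3)
  ba <- bland_altman(a, b)          # differences 0.1, -0.1, 0.3
  expect_equal(ba$bias, 0.1)
  expect_equal(ba$sd_diff, 0.2)
  expect_equal(ba$loa_low, 0.1 - 1.96 * 0.2)
  expect_equal(ba$loa_high, 0.1 + 1.96 * 0.2)
  expect_equal(ba$ci95_high, 0.1 + 1.96 * 0.2 / sqrt(3))

  x <- rnorm(10)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$sd_diff, 0)
  off <- bland_altman(x, x - 0.7)   # constant offset
  expect_equal(off$bias, 0.7)
  expect_equal(off$sd_diff, 0)

  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("bias is antisymmetric in the argument order", {
  set.seed(14)
  a <- rnorm(25); b <- rnorm(25)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
  expect_s3_class(autoplot(bland_altman(a, b)), "ggplot")
})

test_that("pearson_r handles affine, inverted and hand-computed cases", {
  a <- rnorm(10)
  expect_equal(pearson_r(a, 2 * a + 1), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
})

test_that("logistic ROC: separation, null, tie handling vs pair counting", {
  # perfect separation
  r <- auc_logistic(c(1:10, 21:30), rep(c("normal", "glaucoma"), each = 10))
  expect_equal(r$auc, 1)
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[nrow(r$roc)], 1)

  # identical groups: AUC at chance within sampling error
  set.seed(3)
  f <- rnorm(400)
  r0 <- auc_logistic(f, rep(c("a", "b"), 200))
  expect_lt(abs(r0$auc - 0.5), 0.08)

  # ties: brute-force (concordant + half-ties) / (n1 n2) oracle; the
  # logistic score is oriented toward the positive class, so the reported
  # AUC equals the sign-adjusted rank AUC
  set.seed(4)
  for (i in 1:20) {
    feat <- sample(1:4, 24, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), 24, replace = TRUE)
    if (sum(lab) < 2 || sum(!lab) < 2) next
    pos <- feat[lab]; neg <- feat[!lab]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    r1 <- auc_logistic(feat, lab)
    expected <- if (r1$slope >= 0) mean(pairs) else 1 - mean(pairs)
    expect_equal(r1$auc, expected, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under monotone transforms and sign adjustment", {
  set.seed(6)
  feat <- c(rnorm(40, 0), rnorm(40, 1))
  lab <- rep(c(FALSE, TRUE), each = 40)
  a1 <- auc_logistic(feat, lab)$auc
  expect_equal(auc_logistic(exp(feat), lab)$auc, a1)
  # negating the feature flips the fitted slope but not the discrimination
  expect_equal(auc_logistic(-feat, lab)$auc, a1, tolerance = 1e-10)
  # exchanging the class labels mirrors the fit; discrimination is unchanged
  expect_equal(auc_logistic(feat, !lab)$auc, a1, tolerance = 1e-6)
  # the *unadjusted* rank AUC is what flips to 1 - AUC under label exchange
  pos <- feat[lab]; neg <- feat[!lab]
  mw <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  mw_flip <- mean(outer(neg, pos, ">") + 0.5 * outer(neg, pos, "=="))
  expect_equal(mw_flip, 1 - mw, tolerance = 1e-12)
  expect_error(auc_logistic(feat, rep(TRUE, 80)), "two classes|per class")
})

test_that("AUC and ROC agree with an independent implementation (pROC)", {
  set.seed(8)
  feat <- c(rnorm(60, 0, 1), rnorm(60, 0.9, 1.2))
  lab <- rep(c(0, 1), each = 60)
  ours <- auc_logistic(feat, factor(lab))
  ref <- pROC::roc(lab, feat, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("empirical AUC converges to Phi(k/sqrt(2)) for shifted normals", {
  set.seed(12)
  n <- 4000
  k <- 1
  feat <- c(rnorm(n, 10, 2), rnorm(n, 10 + k * 2, 2))
  lab <- rep(c("ctrl", "case"), each = n)
  r <- auc_logistic(feat, factor(lab, levels = c("ctrl", "case")))
  expect_lt(abs(r$auc - pnorm(k / sqrt(2))), 0.02)
  # Hanley-McNeil SE is positive and shrinks with n
  r_small <- auc_logistic(feat[c(1:50, n + (1:50))],
                          lab[c(1:50, n + (1:50))] == "case")
  expect_gt(r_small$se_auc, r$se_auc)
})
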