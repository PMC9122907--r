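#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between two measurement methods from the paired
#' differences: bias (mean difference), its 95% confidence interval, and
#' the 95% limits of agreement (bias +/- 1.96 sd of the differences).
#'
#' @param a,b paired numeric measurements of equal length (n >= 2).
#' @return A `faz_agreement` list: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `ci95_low`, `ci95_high`, `n`, and `data` (tibble of means
#'   and differences for plotting).
#' @examples
#' bland_altman(c(0.30, 0.25, 0.41), c(0.20, 0.35, 0.11))
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("`a` and `b` must have equal length")
  if (length(a) < 2) stop("need at least 2 paired measurements")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    ci95_low = bias - 1.96 * s / sqrt(length(d)),
    ci95_high = bias + 1.96 * s / sqrt(length(d)),
    n = length(d),
    data = tibble::tibble(mean = (a + b) / 2, diff = d)
  ), class = "faz_agreement")
}

#' @export
print.faz_agreement <- function(x, ...) {
  cat(sprintf("<faz_agreement> n = %d\n  bias %.5g (95%% CI %.5g to %.5g)\n",
              x$n, x$bias, x$ci95_low, x$ci95_high))
  cat(sprintf("  limits of agreement %.5g to %.5g (sd %.5g)\n",
              x$loa_low, x$loa_high, x$sd_diff))
  invisible(x)
}

#' Pearson correlation between paired measurements
#'
#' Standard product-moment correlation, with explicit guards for degenerate
#' input (fewer than 3 pairs, or zero variance).
#'
#' @param a,b paired numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(a, b)
}

#' ROC analysis of a single measurement by logistic regression
#'
#' Fits a univariate logistic model for the class given the feature
#' (maximum likelihood via iteratively reweighted least squares), scores
#' the subjects, and computes the ROC curve over all score thresholds with
#' half credit for ties. Because the logistic score is a monotone transform
#' of the feature, the trapezoidal AUC equals the Mann-Whitney rank AUC of
#' the raw feature (sign-adjusted when the fitted slope is negative).
#' The AUC standard error uses the Hanley-McNeil formula.
#'
#' @param feature per-subject scalar measurement (e.g. FAZ area or
#'   perimeter).
#' @param labels two-level factor/logical/character class labels; the
#'   second factor level (or `TRUE`) is the positive class.
#' @return A `faz_roc` list: `auc`, `se_auc`, `ci95_low`, `ci95_high`,
#'   `roc` (tibble of `fpr`, `tpr`), `intercept`, `slope`, `n_pos`,
#'   `n_neg`, `converged`.
#' @export
auc_logistic <- function(feature, labels) {
  if (length(feature) != length(labels))
    stop("`feature` and `labels` must have equal length")
  y <- if (is.logical(labels)) labels else {
    f <- as.factor(labels)
    if (nlevels(f) != 2)
      stop("`labels` must contain exactly two classes, got ", nlevels(f))
    f == levels(f)[2]
  }
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos < 2 || n_neg < 2) stop("need at least 2 subjects per class")

  fit <- suppressWarnings(stats::glm(y ~ feature, family = stats::binomial()))
  score <- stats::fitted(fit)  # already oriented toward the positive class

  # ROC over all thresholds; equal scores collapse to one diagonal segment
  # (trapezoid = half credit for ties)
  ord <- order(score, decreasing = TRUE)
  ys <- y[ord]; ss <- score[ord]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- c(diff(ss) != 0, TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  # Hanley & McNeil (1982) standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
              (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  structure(list(
    auc = auc, se_auc = se,
    ci95_low = max(0, auc - 1.96 * se), ci95_high = min(1, auc + 1.96 * se),
    roc = tibble::tibble(fpr = fpr, tpr = tpr),
    intercept = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]),
    n_pos = n_pos, n_neg = n_neg, converged = fit$converged
  ), class = "faz_roc")
}

#' @export
print.faz_roc <- function(x, ...) {
  cat(sprintf("<faz_roc> AUC %.4f +/- %.4f (95%% CI %.4f-%.4f); %d pos / %d neg\n",
              x$auc, x$se_auc, x$ci95_low, x$ci95_high, x$n_pos, x$n_neg))
  invisible(x)
}
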