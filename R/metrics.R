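#' Overlap metrics between binary masks
#'
#' Jaccard index \eqn{J = |GT \cap P| / |GT \cup P|} and Dice coefficient
#' \eqn{D = 2|GT \cap P| / (|GT| + |P|)} between a ground-truth mask and a
#' predicted mask. Both range from 0 (no similarity) to 1 (perfectly same)
#' and are related by \eqn{D = 2J / (1 + J)}.
#'
#' Conventions for degenerate inputs: if both masks are empty the metrics are
#' 1 (perfect agreement on absence); if exactly one is empty they are 0.
#'
#' @param gt,pred binary masks (matrices or arrays of 0/1 or logical) of
#'   identical shape.
#' @return A scalar in \[0, 1\].
#' @examples
#' gt <- matrix(0, 4, 4); gt[1:2, 1:2] <- 1
#' pred <- matrix(0, 4, 4); pred[1:2, 1:3] <- 1
#' jaccard(gt, pred)
#' dice(gt, pred)
#' @export
jaccard <- function(gt, pred) {
  check_mask_pair(gt, pred)
  inter <- sum(gt == 1 & pred == 1)
  uni <- sum(gt == 1 | pred == 1)
  if (uni == 0) return(1)
  inter / uni
}

#' @rdname jaccard
#' @export
dice <- function(gt, pred) {
  check_mask_pair(gt, pred)
  inter <- sum(gt == 1 & pred == 1)
  tot <- sum(gt == 1) + sum(pred == 1)
  if (tot == 0) return(1)
  2 * inter / tot
}

check_mask_pair <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred)))
    stop("mask shapes differ: ", paste(dim(gt), collapse = "x"), " vs ",
         paste(dim(pred), collapse = "x"))
  bad <- function(m) !all(m %in% c(0, 1, TRUE, FALSE))
  if (bad(gt) || bad(pred))
    stop("masks must contain only 0/1 values")
  invisible(TRUE)
}

#' Soft Dice loss
#'
#' Differentiable relaxation of `1 - D` used as the training loss: set
#' cardinalities are replaced by sums of per-pixel products and values,
#' \deqn{L = 1 - \frac{2\sum p g + s}{\sum p + \sum g + s}}
#' with a small smoothing constant `s` stabilising the empty-mask case.
#' The loss approaches 0 as the probabilities approach the mask.
#'
#' @param gt binary mask.
#' @param prob probability map in \[0, 1\], same shape as `gt`.
#' @param smoothing stabilising constant added to numerator and denominator.
#' @return Scalar loss in \[0, 1\].
#' @export
soft_dice_loss <- function(gt, prob, smoothing = 1e-6) {
  if (!identical(dim(gt), dim(prob)))
    stop("shapes differ: ", paste(dim(gt), collapse = "x"), " vs ",
         paste(dim(prob), collapse = "x"))
  if (any(prob < 0 | prob > 1)) stop("`prob` must lie in [0, 1]")
  if (!all(gt %in% c(0, 1, TRUE, FALSE))) stop("`gt` must be binary")
  num <- 2 * sum(prob * gt) + smoothing
  den <- sum(prob) + sum(gt) + smoothing
  1 - num / den
}

#' Summarise a vector of per-image metric values
#'
#' @param values non-empty numeric vector of per-image metric values.
#' @return A one-row tibble with `n`, `mean` and `sd` (sample standard
#'   deviation; 0 with a warning when `n = 1`).
#' @export
metric_summary <- function(values) {
  if (length(values) == 0) stop("`values` must be non-empty")
  s <- if (length(values) == 1L) {
    warning("standard deviation of a single value reported as 0")
    0
  } else {
    stats::sd(values)
  }
  tibble::tibble(n = length(values), mean = mean(values), sd = s)
}
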