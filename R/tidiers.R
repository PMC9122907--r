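#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects: `tidy()` returns
#' per-observation rows, `glance()` a one-row summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @name fazseg-tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname fazseg-tidiers
#' @method tidy faz_history
#' @export
tidy.faz_history <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname fazseg-tidiers
#' @method glance faz_history
#' @export
glance.faz_history <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(epochs = n,
                 stopped_epoch = attr(x, "stopped_epoch"),
                 stop_reason = attr(x, "stop_reason"),
                 best_epoch = attr(x, "best_epoch"),
                 final_loss = x$loss[n], final_val_loss = x$val_loss[n],
                 final_val_dice = x$val_dice[n])
}

#' @rdname fazseg-tidiers
#' @method tidy faz_eval
#' @export
tidy.faz_eval <- function(x, ...) x$per_image

#' @rdname fazseg-tidiers
#' @method glance faz_eval
#' @export
glance.faz_eval <- function(x, ...) x$summary

#' @rdname fazseg-tidiers
#' @method tidy faz_agreement
#' @export
tidy.faz_agreement <- function(x, ...) x$data

#' @rdname fazseg-tidiers
#' @method glance faz_agreement
#' @export
glance.faz_agreement <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, ci95_low = x$ci95_low,
                 ci95_high = x$ci95_high, n = x$n)
}

#' @rdname fazseg-tidiers
#' @method tidy faz_roc
#' @export
tidy.faz_roc <- function(x, ...) x$roc

#' @rdname fazseg-tidiers
#' @method glance faz_roc
#' @export
glance.faz_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, se_auc = x$se_auc, ci95_low = x$ci95_low,
                 ci95_high = x$ci95_high, intercept = x$intercept,
                 slope = x$slope, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname fazseg-tidiers
#' @method tidy faz_replicates
#' @export
tidy.faz_replicates <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname fazseg-tidiers
#' @method glance faz_replicates
#' @export
glance.faz_replicates <- function(x, ...) {
  q <- attr(x, "quartiles")
  tibble::tibble(n_repeats = nrow(x), mean = mean(x$mean_dice),
                 q1 = q[1], median = q[2], q3 = q[3],
                 iqr = attr(x, "iqr"), spread = attr(x, "spread"))
}

# --------------------------------------------------------------- autoplot --

#' Plots for result objects
#'
#' `autoplot()` methods: training curves for a `faz_history`, a
#' Bland-Altman scatter for a `faz_agreement`, the ROC curve for a
#' `faz_roc`, and a boxplot of per-repeat test Dice for `faz_replicates`.
#'
#' @param object a result object.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @name fazseg-plots
NULL

#' @export
ggplot2::autoplot

#' @rdname fazseg-plots
#' @method autoplot faz_history
#' @export
autoplot.faz_history <- function(object, ...) {
  d <- tidy(object)
  long <- tibble::tibble(
    epoch = rep(d$epoch, 2),
    dice = c(d$dice, d$val_dice),
    split = rep(c("training", "validation"), each = nrow(d))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$dice,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "Dice coefficient", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fazseg-plots
#' @method autoplot faz_agreement
#' @export
autoplot.faz_agreement <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "mean of methods", y = "difference") +
    ggplot2::theme_minimal()
}

#' @rdname fazseg-plots
#' @method autoplot faz_roc
#' @export
autoplot.faz_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f +/- %.3f", object$auc,
                                     object$se_auc)) +
    ggplot2::theme_minimal()
}

#' @rdname fazseg-plots
#' @method autoplot faz_replicates
#' @export
autoplot.faz_replicates <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$mean_dice)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "test-set mean Dice") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
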