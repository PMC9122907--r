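#' Training configuration
#'
#' Hyperparameters of the training protocol: adaptive-moment (Adam)
#' optimisation with a reduced learning rate, small batches with per-epoch
#' shuffling, Dice loss, and early stopping on the validation loss.
#'
#' The second-moment decay defaults to 0.99 (the protocol's stated value;
#' the conventional Adam default 0.999 can be selected explicitly).
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param epsilon Adam stabiliser.
#' @param batch_size images per gradient step.
#' @param shuffle reshuffle the training set every epoch.
#' @param max_epochs maximum number of epochs.
#' @param early_stopping monitor the validation loss and stop early.
#' @param min_delta minimum improvement in validation loss that resets the
#'   patience counter.
#' @param patience epochs without improvement tolerated before stopping.
#' @param loss `"dice"` (soft Dice loss) or `"mse"`.
#' @param restore_best restore the weights of the best validation epoch
#'   when stopping early.
#' @param seed seed for shuffling (weight initialisation is seeded by
#'   [build_model()]).
#' @return A `faz_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.99,
                         epsilon = 1e-7, batch_size = 5L, shuffle = TRUE,
                         max_epochs = 500L, early_stopping = TRUE,
                         min_delta = 1e-8, patience = 40L,
                         loss = c("dice", "mse"), restore_best = TRUE,
                         seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, batch_size >= 1, patience >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 shuffle = isTRUE(shuffle), max_epochs = as.integer(max_epochs),
                 early_stopping = isTRUE(early_stopping), min_delta = min_delta,
                 patience = as.integer(patience), loss = loss,
                 restore_best = isTRUE(restore_best), seed = as.integer(seed)),
            class = "faz_train_config")
}

check_training_arrays <- function(model, x, y, what) {
  d <- dim(x)
  cfg <- model$config
  if (length(d) != 4L)
    stop(what, " images must be an H x W x C x N array")
  if (d[4] == 0L) stop(what, " set is empty")
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2] ||
      d[3] != cfg$input_channels)
    stop(what, " images are ", paste(d[1:3], collapse = "x"),
         " but the model expects ",
         paste(c(cfg$input_size, cfg$input_channels), collapse = "x"))
  if (!identical(dim(y)[c(1, 2, 4)], d[c(1, 2, 4)]))
    stop(what, " masks do not match the images")
  invisible(TRUE)
}

# replicate single-channel masks across the model's output channels
mask_targets <- function(model, masks) {
  out_ch <- model$config$output_channels
  if (length(dim(masks)) == 3L)
    dim(masks) <- c(dim(masks)[1:2], 1L, dim(masks)[3])
  if (dim(masks)[3] == 1L && out_ch > 1L)
    masks <- masks[, , rep(1L, out_ch), , drop = FALSE]
  masks
}

#' Train a model
#'
#' Runs the training protocol: Adam updates on shuffled mini-batches,
#' per-epoch evaluation of training and validation loss and Dice (the Dice
#' metric is computed on predictions thresholded at 0.5, matching the
#' test-time pipeline), early stopping on the validation loss, and optional
#' restoration of the best-epoch weights. With a fixed model seed and
#' configuration seed, repeated runs are bit-identical.
#'
#' @param model a freshly built `faz_model` (modified in place).
#' @param x_train,y_train training images (H x W x C x N) and masks
#'   (H x W x N or H x W x 1 x N, values 0/1).
#' @param x_val,y_val validation images and masks.
#' @param config a [train_config()].
#' @param verbose print one line per epoch to `stderr`.
#' @return A list with elements `model` (the trained model) and `history`
#'   (class `faz_history`: a tibble of per-epoch `loss`, `val_loss`, `dice`,
#'   `val_dice`, with attributes `stopped_epoch` and `stop_reason`).
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "faz_model"), inherits(config, "faz_train_config"))
  y_train <- mask_targets(model, y_train)
  y_val <- mask_targets(model, y_val)
  check_training_arrays(model, x_train, y_train, "training")
  check_training_arrays(model, x_val, y_val, "validation")

  n <- dim(x_train)[4]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  hist <- vector("list", config$max_epochs)
  best_loss <- Inf
  best_weights <- NULL
  best_epoch <- 0L
  wait <- 0L
  stop_reason <- "max_epochs"
  stopped_epoch <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    tr_loss <- 0; tr_dice <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      r <- nn_train_batch(model$ptr,
                          x_train[, , , idx, drop = FALSE],
                          y_train[, , , idx, drop = FALSE],
                          config$loss, config$learning_rate, config$beta1,
                          config$beta2, config$epsilon)
      tr_loss <- tr_loss + r$loss; tr_dice <- tr_dice + r$dice; nb <- nb + 1L
    }
    ev <- nn_eval(model$ptr, x_val, y_val, config$loss)
    hist[[epoch]] <- c(loss = tr_loss / nb, val_loss = ev$loss,
                       dice = tr_dice / nb, val_dice = ev$dice)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val_loss %.4f  val_D %.4f",
                      epoch, tr_loss / nb, ev$loss, ev$dice))
    if (ev$loss < best_loss - config$min_delta) {
      best_loss <- ev$loss
      wait <- 0L
      best_epoch <- epoch
      if (config$restore_best) best_weights <- nn_get_weights(model$ptr)
    } else if (config$early_stopping) {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stop_reason <- "early_stop"
        stopped_epoch <- epoch
        break
      }
    }
  }
  if (stop_reason == "early_stop" && config$restore_best &&
      !is.null(best_weights))
    nn_set_weights(model$ptr, best_weights)

  hist <- hist[!vapply(hist, is.null, logical(1))]
  history <- tibble::as_tibble(do.call(rbind, hist))
  history <- tibble::add_column(history, epoch = seq_len(nrow(history)),
                                .before = 1)
  attr(history, "stopped_epoch") <- min(stopped_epoch, nrow(history))
  attr(history, "stop_reason") <- stop_reason
  attr(history, "best_epoch") <- best_epoch
  class(history) <- c("faz_history", class(history))
  list(model = model, history = history)
}

#' Replicate-training reproducibility experiment
#'
#' Trains the same architecture repeatedly under identical conditions,
#' varying only the per-repeat seed stream, and reports the spread of the
#' test-set mean Dice — the spread quantifies how reproducible training is.
#'
#' @param arch a `faz_arch` configuration.
#' @param config a [train_config()]; repeat `i` uses seed
#'   `config$seed + i - 1` for both weight initialisation and shuffling.
#' @param n_repeats number of training repeats (>= 2).
#' @param dataset list with `x_train`, `y_train`, `x_val`, `y_val`,
#'   `x_test`, `y_test` arrays.
#' @param threshold binarisation threshold for the test-set Dice.
#' @param seeds optional explicit per-repeat seeds (length `n_repeats`),
#'   overriding the default `config$seed + i - 1` stream (e.g. to force
#'   identical repeats).
#' @return A `faz_replicates` object: a tibble with one row per repeat
#'   (`repeat`, `seed`, `mean_dice`, `stopped_epoch`) plus boxplot
#'   statistics (`quartiles`, `iqr`, `spread`) as attributes.
#' @export
replicate_training <- function(arch, config, n_repeats, dataset,
                               threshold = 0.5, seeds = NULL) {
  if (n_repeats < 2) stop("`n_repeats` must be >= 2")
  if (!is.null(seeds) && length(seeds) != n_repeats)
    stop("`seeds` must have length `n_repeats`")
  rows <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    seed_i <- if (is.null(seeds)) config$seed + i - 1L else as.integer(seeds[i])
    cfg_i <- config
    cfg_i$seed <- seed_i
    model <- build_model(arch, seed = seed_i)
    fit <- train_model(model, dataset$x_train, dataset$y_train,
                       dataset$x_val, dataset$y_val, cfg_i)
    ev <- evaluate_testset(fit$model, dataset$x_test, dataset$y_test,
                           threshold = threshold)
    rows[[i]] <- tibble::tibble(
      run = i, seed = seed_i,
      mean_dice = mean(ev$per_image$dice_raw),
      stopped_epoch = attr(fit$history, "stopped_epoch")
    )
  }
  out <- dplyr::bind_rows(rows)
  q <- stats::quantile(out$mean_dice, c(0.25, 0.5, 0.75), names = FALSE)
  attr(out, "quartiles") <- q
  attr(out, "iqr") <- q[3] - q[1]
  attr(out, "spread") <- max(out$mean_dice) - min(out$mean_dice)
  class(out) <- c("faz_replicates", class(out))
  out
}

#' Evaluate a trained model on a test set
#'
#' For each test image the prediction is binarised at `threshold` and
#' compared with the ground truth (raw Dice); the segmented regions are
#' labelled, any regions beyond the first are counted as extra contours, and
#' the Dice is recomputed after keeping only the largest region (with
#' enclosed holes filled) — the "largest contour" Dice. Removing small
#' spurious regions typically raises the Dice slightly.
#'
#' @param model a trained `faz_model`.
#' @param images H x W x C x N test images (or a list of H x W x C arrays).
#' @param masks H x W x N ground-truth masks (0/1).
#' @param threshold binarisation threshold.
#' @return A `faz_eval` object: list with `per_image` (tibble: `image`,
#'   `dice_raw`, `dice_largest`, `n_regions`, `extra_contours`) and
#'   `summary` (tibble with means/SDs, images with multiple regions, total
#'   extra contours).
#' @export
evaluate_testset <- function(model, images, masks, threshold = 0.5) {
  x <- as_batch_array(images, channels = model$config$input_channels)
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  n <- dim(x)[4]
  if (dim(masks)[3] != n) stop("number of masks does not match images")
  if (n == 0L) stop("empty test set")
  prob <- predict(model, x)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gt <- masks[, , i]
    pred <- binarize(prob[, , i], threshold)
    d_raw <- dice(gt, pred)
    lab <- cc_label8(pred)
    k <- attr(lab, "n")
    if (k == 0L) {
      rows[[i]] <- tibble::tibble(image = i, dice_raw = d_raw,
                                  dice_largest = d_raw, n_regions = 0L,
                                  extra_contours = 0L)
      next
    }
    sizes <- cc_sizes(lab)
    keep <- which.max(sizes)
    largest <- fill_holes(lab == keep)
    rows[[i]] <- tibble::tibble(image = i, dice_raw = d_raw,
                                dice_largest = dice(gt, largest),
                                n_regions = as.integer(k),
                                extra_contours = as.integer(k - 1L))
  }
  per_image <- dplyr::bind_rows(rows)
  summary <- tibble::tibble(
    n_images = n,
    mean_dice = mean(per_image$dice_raw),
    sd_dice = if (n > 1) stats::sd(per_image$dice_raw) else 0,
    mean_dice_largest = mean(per_image$dice_largest),
    sd_dice_largest = if (n > 1) stats::sd(per_image$dice_largest) else 0,
    images_multi_region = sum(per_image$n_regions > 1L),
    total_extra_contours = sum(per_image$extra_contours)
  )
  structure(list(per_image = per_image, summary = summary),
            class = "faz_eval")
}

#' @export
print.faz_eval <- function(x, ...) {
  cat("<faz_eval> ", x$summary$n_images, " images\n", sep = "")
  cat(sprintf("  mean D (raw)     %.4f  (sd %.4f)\n",
              x$summary$mean_dice, x$summary$sd_dice))
  cat(sprintf("  mean D (largest) %.4f  (sd %.4f)\n",
              x$summary$mean_dice_largest, x$summary$sd_dice_largest))
  cat("  images with >1 region: ", x$summary$images_multi_region,
      "; extra contours: ", x$summary$total_extra_contours, "\n", sep = "")
  invisible(x)
}

# fill 4-connected background holes fully enclosed by a logical mask
fill_holes <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  bg <- cc_label4_bg(m)
  nb <- attr(bg, "n")
  if (nb == 0L) return(m)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole <- bg > 0 & !(bg %in% border_ids)
  m[hole] <- 1L
  m
}

#' Save / load a model checkpoint
#'
#' A checkpoint is the serialized weight state (`<path>`) plus a JSON
#' sidecar (`<path>.json`) holding the architecture configuration, so a
#' checkpoint is self-describing.
#'
#' @param model a `faz_model`.
#' @param path file path for the weight state.
#' @return `save_model` returns `path` invisibly; `load_model` returns a
#'   rebuilt `faz_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model_weights(model), path)
  cfg <- unclass(model$config)
  cfg$midblock_min_channels <- cfg$midblock_min_channels %||% NA
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arch <- arch_config(
    input_size = cfg$input_size, input_channels = cfg$input_channels,
    width_policy = cfg$width_policy, base_width = cfg$base_width,
    depth = cfg$depth, attention = cfg$attention,
    bottleneck_attention = cfg$bottleneck_attention,
    skip_mode = cfg$skip_mode, up_mode = cfg$up_mode,
    midblock_min_channels = if (is.na(cfg$midblock_min_channels)) NULL else
      cfg$midblock_min_channels,
    dropout_rate = cfg$dropout_rate, output_channels = cfg$output_channels
  )
  model <- build_model(arch)
  set_model_weights(model, readRDS(path))
  model
}
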