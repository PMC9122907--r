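# one small training run shared by several assertions below
trained_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ds <- tiny_dataset(21, size = 32, seed = 50)
    arr <- dataset_arrays(ds)
    model <- build_model(tiny_arch(32, 16, mid = 2), seed = 1)
    tc <- train_config(learning_rate = 3e-3, batch_size = 5,
                       max_epochs = 14, early_stopping = FALSE, seed = 1)
    fit <- train_model(model, arr$x[, , , 1:16], arr$y[, , 1:16],
                       arr$x[, , , 17:18], arr$y[, , 17:18], tc)
    cache <<- list(ds = ds, arr = arr, fit = fit, tc = tc)
    cache
  }
})

test_that("training learns the synthetic task and logs a coherent history", {
  fx <- trained_fixture()
  h <- fx$fit$history
  expect_equal(nrow(h), 14L)
  expect_named(h, c("epoch", "loss", "val_loss", "dice", "val_dice"))
  expect_equal(attr(h, "stop_reason"), "max_epochs")
  # learning-progress check: final validation Dice above the first epoch's
  expect_gt(h$val_dice[nrow(h)], h$val_dice[1])
  expect_gt(h$val_dice[nrow(h)], 0.5)
  g <- glance(h)
  expect_equal(g$epochs, 14L)
  expect_s3_class(autoplot(h), "ggplot")
})

test_that("training is bit-reproducible under a fixed seed", {
  fx <- trained_fixture()
  model2 <- build_model(tiny_arch(32, 16, mid = 2), seed = 1)
  fit2 <- train_model(model2, fx$arr$x[, , , 1:16], fx$arr$y[, , 1:16],
                      fx$arr$x[, , , 17:18], fx$arr$y[, , 17:18], fx$tc)
  expect_identical(as.data.frame(fx$fit$history), as.data.frame(fit2$history))
  p1 <- predict(fx$fit$model, fx$arr$x[, , , 19])
  p2 <- predict(fit2$model, fx$arr$x[, , , 19])
  expect_identical(p1, p2)
})

test_that("input validation rejects empty sets and mismatched shapes", {
  m <- build_model(tiny_arch(32, 4), seed = 1)
  x <- array(0.5, c(32, 32, 3, 2)); y <- array(0L, c(32, 32, 2))
  bad <- array(0.5, c(16, 16, 3, 2))
  tc <- train_config(max_epochs = 1)
  expect_error(train_model(m, bad, array(0L, c(16, 16, 2)), x, y, tc),
               "expects")
  expect_error(train_model(m, x[, , , 0, drop = FALSE],
                           y[, , 0, drop = FALSE], x, y, tc), "empty")
})

test_that("early stopping waits out its patience and restores best weights", {
  ds <- tiny_dataset(6, size = 32, seed = 77)
  arr <- dataset_arrays(ds)
  m <- build_model(tiny_arch(32, 4), seed = 2)
  # learning rate so small that the validation loss cannot improve by
  # min_delta: the first epoch sets the best, patience runs out after it
  tc <- train_config(learning_rate = 1e-12, min_delta = 1e-3, patience = 3,
                     max_epochs = 50, seed = 2)
  fit <- train_model(m, arr$x[, , , 1:4], arr$y[, , 1:4],
                     arr$x[, , , 5:6, drop = FALSE], arr$y[, , 5:6], tc)
  h <- fit$history
  expect_equal(attr(h, "stop_reason"), "early_stop")
  expect_equal(nrow(h), 1L + 3L)   # never triggers before patience elapses
  expect_equal(attr(h, "best_epoch"), 1L)
})

test_that("test-set evaluation separates raw and largest-region Dice", {
  fx <- trained_fixture()
  ev <- evaluate_testset(fx$fit$model, fx$arr$x[, , , 19:21, drop = FALSE],
                         fx$arr$y[, , 19:21])
  expect_equal(nrow(ev$per_image), 3L)
  expect_true(all(ev$per_image$extra_contours >= 0))
  # ground truths are single-region: dropping spurious extra regions cannot
  # hurt on average
  expect_gte(ev$summary$mean_dice_largest, ev$summary$mean_dice - 1e-9)
  expect_gte(ev$summary$mean_dice, 0.5)
  expect_s3_class(tidy(ev), "tbl_df")
})

test_that("largest-region selection logic on a constructed two-region case", {
  # prediction with one large and one small disjoint region vs a
  # single-region ground truth
  gt <- matrix(0L, 24, 24); gt[4:14, 4:14] <- 1L
  pred <- matrix(0L, 24, 24); pred[4:13, 4:13] <- 1L; pred[20:22, 20:22] <- 1L
  lab <- cc_label8_pkg(pred)
  expect_equal(attr(lab, "n"), 2L)             # one extra contour
  sizes <- fazseg:::cc_sizes(lab)
  largest <- matrix(as.integer(lab == which.max(sizes)), 24, 24)
  expect_gt(dice(gt, largest), dice(gt, pred)) # removing the extra helps
})

test_that("all-background predictions give zero Dice without errors", {
  gt <- matrix(0L, 16, 16); gt[5:9, 5:9] <- 1L
  expect_equal(dice(gt, matrix(0L, 16, 16)), 0)
  res <- measure_mask(matrix(0L, 16, 16))
  expect_true(res$no_faz)
})

test_that("checkpoints round-trip through save_model/load_model", {
  fx <- trained_fixture()
  path <- tempfile(fileext = ".rds")
  save_model(fx$fit$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  x <- fx$arr$x[, , , 20]
  expect_equal(predict(fx$fit$model, x), predict(m2, x), tolerance = 1e-7)
})

test_that("replicate training reports per-repeat results and spread", {
  ds <- tiny_dataset(10, size = 32, seed = 31)
  arr <- dataset_arrays(ds)
  dataset <- list(x_train = arr$x[, , , 1:6], y_train = arr$y[, , 1:6],
                  x_val = arr$x[, , , 7:8, drop = FALSE], y_val = arr$y[, , 7:8],
                  x_test = arr$x[, , , 9:10, drop = FALSE], y_test = arr$y[, , 9:10])
  arch <- tiny_arch(32, 4)
  tc <- train_config(learning_rate = 2e-3, batch_size = 3, max_epochs = 2,
                     early_stopping = FALSE, seed = 5)
  expect_error(replicate_training(arch, tc, 1, dataset), ">= 2")

  # forcing identical seeds forces identical repeats: zero spread
  same <- replicate_training(arch, tc, 2, dataset, seeds = c(9, 9))
  expect_equal(attr(same, "spread"), 0)

  reps <- replicate_training(arch, tc, 3, dataset)
  expect_equal(reps$seed, c(5, 6, 7))
  expect_true(all(is.finite(reps$mean_dice)))
  expect_true(all(reps$mean_dice >= 0 & reps$mean_dice <= 1))
  expect_s3_class(autoplot(reps), "ggplot")
  expect_equal(glance(reps)$n_repeats, 3L)
})
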