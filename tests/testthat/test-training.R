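test_that("chronological split allocates 6:2:2 with remainder to train", {
  s <- split_dataset(3600)
  expect_equal(lengths(s[c("train", "validation", "test")]),
               c(train = 2160, validation = 720, test = 720))
  s10 <- split_dataset(10)
  expect_equal(lengths(s10[c("train", "validation", "test")]),
               c(train = 6, validation = 2, test = 2))
  s17 <- split_dataset(1747)
  expect_equal(lengths(s17[c("train", "validation", "test")]),
               c(train = 1049, validation = 349, test = 349))
  expect_error(split_dataset(9), "at least 10")
  # partitions are disjoint and exhaustive
  all_idx <- sort(c(s17$train, s17$validation, s17$test))
  expect_identical(all_idx, 1:1747)
})

test_that("boundary-crossing samples are purged from validation and test", {
  s <- split_dataset(1747, span = 50)
  expect_equal(unname(s$dropped), c(49L, 49L))
  # no frame of a validation sample overlaps a training sample's span
  expect_gt(min(s$validation), max(s$train) + 49)
  expect_gt(min(s$test), max(s$train) + length(s$validation) + 49 + 49)
})

test_that("learning rate halves every 50 epochs from 0.001", {
  cfg <- training_config()
  expect_equal(lr_schedule(0, cfg), 0.001)
  expect_equal(lr_schedule(49, cfg), 0.001)
  expect_equal(lr_schedule(50, cfg), 0.0005)
  expect_equal(lr_schedule(199, cfg), 0.000125)
})

test_that("training runs deterministically and records curves", {
  ds <- tiny_dataset()
  sp <- split_dataset(ds)
  cfg <- fno_config(num_layers = 2, width = 4, modes = 3)
  run <- function() train_model(fno_init(cfg, seed = 1), ds,
                                sp$train[1:60], sp$validation,
                                training_config(epochs = 2, seed = 3))
  r1 <- run(); r2 <- run()
  expect_identical(r1$model$params, r2$model$params)
  expect_equal(nrow(r1$curves), 2)
  expect_true(all(is.finite(r1$curves$train_mse)))
  expect_true(all(is.finite(r1$curves$val_mse)))
  # zero epochs returns the initialized model with empty curves
  r0 <- train_model(fno_init(cfg, seed = 1), ds, sp$train[1:60],
                    integer(0), training_config(epochs = 0, seed = 3))
  expect_equal(nrow(r0$curves), 0)
  expect_false(is.null(r0$model$normalizer))
})

test_that("training reduces validation error on a synthetic subject", {
  ds <- tiny_dataset(20)
  sp <- split_dataset(ds)
  cfg <- fno_config(num_layers = 2, width = 6, modes = 4)
  r <- train_model(fno_init(cfg, seed = 2), ds, sp$train, sp$validation,
                   training_config(epochs = 12, seed = 4))
  expect_lt(tail(r$curves$val_mse, 1), r$curves$val_mse[1])
})

test_that("MSE evaluation is invariant to sample order", {
  ds <- tiny_dataset()
  sp <- split_dataset(ds)
  cfg <- fno_config(num_layers = 1, width = 4, modes = 3)
  m <- train_model(fno_init(cfg, seed = 1), ds, sp$train[1:40],
                   integer(0), training_config(epochs = 1, seed = 1))$model
  idx <- sp$test
  expect_equal(evaluate_mse(m, ds, idx),
               evaluate_mse(m, ds, rev(idx)), tolerance = 1e-12)
})

test_that("model comparison reports per-subject ratios", {
  mat <- matrix(c(1, 3, 4, 2), 2, 2)
  fno <- structure(list(mse_matrix = mat), class = "eval_report")
  cnn <- structure(list(mse_matrix = 2 * mat), class = "eval_report")
  cmp <- compare_models(fno, cnn)
  expect_equal(unname(cmp$ratio), c(2, 2))
  expect_true(cmp$fno_never_worse)
  same <- compare_models(fno, fno)
  expect_equal(unname(same$ratio), c(1, 1))
  # ratio ordering is invariant under common rescaling
  cnn10 <- structure(list(mse_matrix = 20 * mat), class = "eval_report")
  fno10 <- structure(list(mse_matrix = 10 * mat), class = "eval_report")
  expect_equal(compare_models(fno10, cnn10)$ratio, cmp$ratio)
})

test_that("checkpoints round-trip a trained model", {
  ds <- tiny_dataset()
  cfg <- fno_config(num_layers = 1, width = 4, modes = 3)
  m <- train_model(fno_init(cfg, seed = 1), ds, 1:40, integer(0),
                   training_config(epochs = 1, seed = 1))$model
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$normalizer, m$normalizer)
  x <- array(rnorm(11 * 11 * 30), c(11, 11, 30))
  expect_identical(fno_forward(m, x), fno_forward(m2, x))
})
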