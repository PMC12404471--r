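# FramePredictor construction, head shapes, checkpointing, short training.

test_that("head shapes follow the study channel depth", {
  sc5 <- study_config("cells_stage", H = 16, W = 16)
  m5 <- build_frame_predictor(model_config(sc5, "tiny",
                                           filters = c(2L, 2L, 2L, 2L),
                                           kernels = c(3L, 3L, 3L, 1L)))
  w <- array(runif(16 * 16 * 5 * 7), c(16, 16, 5, 7))
  p <- predict_next_frame(m5, w)
  expect_identical(dim(p$full), c(16L, 16L, 5L))
  expect_identical(dim(p$image), c(16L, 16L, 3L))

  sc4 <- study_config("blastocyst", H = 16, W = 16)
  m4 <- build_frame_predictor(model_config(sc4, "tiny",
                                           filters = c(2L, 2L, 2L, 2L),
                                           kernels = c(3L, 3L, 3L, 1L)))
  w4 <- array(runif(16 * 16 * 4 * 7), c(16, 16, 4, 7))
  p4 <- predict_next_frame(m4, w4)
  expect_identical(dim(p4$full), c(16L, 16L, 4L))
  expect_identical(dim(p4$image), c(16L, 16L, 3L))
  # wrong channel depth is rejected
  expect_error(predict_next_frame(m5, w4), "window")
})

test_that("paper preset carries the published architecture constants", {
  mc <- model_config(study_config("cells_stage"), "paper")
  expect_identical(mc$filters, c(32L, 64L, 128L, 128L))
  expect_identical(mc$kernels, c(7L, 5L, 3L, 1L))
  expect_equal(mc$dropout_rate, 0.25)
  expect_identical(mc$head_kernel, 3L)
  expect_identical(unname(mc$input_shape), c(7L, 128L, 128L, 5L))
})

test_that("default train config matches the training protocol", {
  tc <- train_config()
  expect_identical(tc$epochs, 50L)
  expect_identical(tc$batch_size, 2L)
  expect_equal(tc$learning_rate, 1e-4)
  expect_identical(tc$checkpoint_metric, "val_accuracy")
})

test_that("a short training run learns and keeps the best-metric epoch", {
  pv <- fix_pvideo15()
  pairs <- build_subsequences(pv)
  model <- fix_tiny_predictor()
  tcfg <- train_config(epochs = 3, batch_size = 2, learning_rate = 3e-3,
                       rng_seed = 5)
  trained <- train_predictor(model, pairs[1:6], pairs[7:8], tcfg)
  h <- trained$training$history
  expect_identical(nrow(h), 3L)
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_identical(trained$training$selected_epoch,
                   which.max(h$val_accuracy))
  expect_error(train_predictor(model, list(), pairs[7:8], tcfg), "non-empty")
})

test_that("checkpoints round-trip exactly and refuse mismatched shapes", {
  dir <- withr::local_tempdir()
  pv <- fix_pvideo15()
  model <- fix_tiny_predictor()
  w <- pv$frames[, , , 1:7, drop = FALSE]
  before <- predict_next_frame(model, w)
  path <- file.path(dir, "ck.rds")
  save_checkpoint(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$model_config$study, "cells_stage")
  expect_identical(meta$n_params, length(model$par))
  loaded <- load_checkpoint(path)
  expect_identical(predict_next_frame(loaded, w), before)
  expect_error(load_checkpoint(path, expect_C = 4), "channel depth")
})

test_that("persistence baseline equals the mean squared frame difference", {
  pv <- fix_pvideo15()
  pairs <- build_subsequences(pv)
  oracle <- mean(vapply(pairs, function(p) {
    mean((p$input[, , 1:3, 7] - p$target_image)^2)
  }, numeric(1)))
  expect_equal(persistence_mse(pairs), oracle)
})
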