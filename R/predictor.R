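# FramePredictor: a four-layer ConvLSTM network with two parallel
# convolutional output heads. Head 1 predicts the full C-channel next frame
# (so it can be fed back recursively), head 2 predicts the 3-channel image
# that all quality metrics are computed on. Both heads end in sigmoids and
# the training loss is the sum of their mean binary cross entropies.

#' Model configuration for the FramePredictor
#'
#' The `"paper"` preset is the full-scale architecture: ConvLSTM layers with
#' 32/64/128/128 filters, kernel sizes 7/5/3/1, normalization after the
#' first three layers, dropout 0.25 after the last, and two kernel-3 sigmoid
#' convolution heads. The `"tiny"` preset (filters 4/8/16/16, same kernels)
#' is sized so that training runs in minutes on a single CPU with the
#' package's own compute core; it is the preset used throughout the test
#' suite, together with 64 x 64 frames.
#'
#' @param study_cfg A [study_config()]; supplies the input shape (F, H, W, C).
#' @param scale_preset `"paper"` or `"tiny"`.
#' @param filters,kernels,dropout_rate,head_kernel,activation Overrides for
#'   individual architecture constants.
#' @param precision `"single"` (training throughput) or `"double"`.
#' @return A `model_config` list.
#' @export
model_config <- function(study_cfg, scale_preset = c("paper", "tiny"),
                         filters = NULL, kernels = c(7L, 5L, 3L, 1L),
                         dropout_rate = 0.25, head_kernel = 3L,
                         activation = "relu",
                         precision = c("single", "double")) {
  precision <- match.arg(precision)
  stopifnot(inherits(study_cfg, "study_config"))
  scale_preset <- match.arg(scale_preset)
  if (is.null(filters)) {
    filters <- if (scale_preset == "paper") c(32L, 64L, 128L, 128L)
               else c(4L, 8L, 16L, 16L)
  }
  stopifnot(length(filters) == 4, length(kernels) == 4)
  structure(list(scale_preset = scale_preset,
                 filters = as.integer(filters), kernels = as.integer(kernels),
                 dropout_rate = dropout_rate, head_kernel = as.integer(head_kernel),
                 activation = activation,
                 precision = precision,
                 input_shape = c(F = study_cfg$F, H = study_cfg$H,
                                 W = study_cfg$W, C = study_cfg$C),
                 study = study_cfg$study,
                 time_window = study_cfg$time_window,
                 max_cell_count = study_cfg$max_cell_count),
            class = "model_config")
}

#' Training configuration for the FramePredictor
#'
#' Full-scale defaults: batch size 2, Adam with learning rate 1e-4, binary
#' cross entropy, 50 epochs for the cleavage-stage study (35 for the
#' blastocyst study), checkpoint selection by the highest head-2 validation
#' accuracy.
#'
#' @param epochs Number of passes over the training pairs.
#' @param batch_size Gradient-accumulation batch size.
#' @param learning_rate Adam step size.
#' @param loss Loss name (only `"bce"` is implemented).
#' @param checkpoint_metric `"val_accuracy"` (mean binary accuracy of head 2
#'   at threshold 0.5) or `"val_loss"`.
#' @param rng_seed Seed for shuffling, dropout masks and subsampling.
#' @param steps_per_epoch Optional cap on training pairs visited per epoch
#'   (seeded subsample); `NULL` uses all pairs.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 2L, learning_rate = 1e-4,
                         loss = "bce",
                         checkpoint_metric = c("val_accuracy", "val_loss"),
                         rng_seed = 1L, steps_per_epoch = NULL) {
  checkpoint_metric <- match.arg(checkpoint_metric)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, loss == "bce")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 checkpoint_metric = checkpoint_metric,
                 rng_seed = as.integer(rng_seed),
                 steps_per_epoch = steps_per_epoch),
            class = "train_config")
}

fp_cpp_cfg <- function(mcfg) {
  list(H = unname(mcfg$input_shape["H"]), W = unname(mcfg$input_shape["W"]),
       C = unname(mcfg$input_shape["C"]), F = unname(mcfg$input_shape["F"]),
       filters = mcfg$filters, kernels = mcfg$kernels,
       head_kernel = mcfg$head_kernel, activation = mcfg$activation,
       precision = mcfg$precision %||% "double")
}

fp_shapes_list <- function(mcfg) {
  sh <- cpp_fp_shapes(fp_cpp_cfg(mcfg))
  lapply(sh, function(d) c(d[1], d[2]))
}

#' Build a FramePredictor
#'
#' Assembles the ConvLSTM stack described by the model config and
#' initializes its parameters (Glorot-uniform weights, forget-gate biases at
#' 1). Head 1 matches the study's channel depth (128 x 128 x 5 cleavage,
#' 128 x 128 x 4 blastocyst at full scale); head 2 is always 3-channel.
#'
#' @param mcfg A [model_config()].
#' @param seed Weight-initialization seed.
#' @return A `frame_predictor` object.
#' @export
build_frame_predictor <- function(mcfg, seed = 1L) {
  stopifnot(inherits(mcfg, "model_config"))
  shapes <- fp_shapes_list(mcfg)
  par <- nn_init_params(shapes, seed)
  structure(list(par = par, mcfg = mcfg, shapes = shapes,
                 init_seed = as.integer(seed), training = NULL),
            class = "frame_predictor")
}

#' @export
print.frame_predictor <- function(x, ...) {
  is <- x$mcfg$input_shape
  cat(sprintf("FramePredictor (%s preset, %s study)\n", x$mcfg$scale_preset,
              x$mcfg$study))
  cat(sprintf("  input %d x %d x %d x %d, filters %s, %s parameters\n",
              is["F"], is["H"], is["W"], is["C"],
              paste(x$mcfg$filters, collapse = "/"),
              format(length(x$par), big.mark = ",")))
  if (!is.null(x$training)) {
    cat(sprintf("  trained %d epochs, checkpoint at epoch %d (%s = %.4f)\n",
                nrow(x$training$history), x$training$selected_epoch,
                x$training$metric, x$training$best_metric))
  }
  invisible(x)
}

fp_loss_grad <- function(par, ccfg, pair, dropmask) {
  cpp_fp_run(par, ccfg, pair$input, dropmask, pair$target, pair$target_image,
             TRUE)
}

fp_eval_pair <- function(par, ccfg, pair) {
  r <- cpp_fp_run(par, ccfg, pair$input, NULL, pair$target, pair$target_image,
                  FALSE)
  H <- dim(pair$target)[1]; W <- dim(pair$target)[2]
  p2 <- array(r$head2, c(H, W, 3))
  acc <- mean((p2 > 0.5) == (pair$target_image > 0.5))
  mse <- mean((p2 - pair$target_image)^2)
  c(loss = r$loss, acc = acc, mse = mse)
}

#' Train the FramePredictor
#'
#' Minimizes the summed mean binary cross entropy of both heads with Adam
#' and gradient accumulation over `batch_size` windows. After every epoch the
#' validation loss and head-2 binary accuracy are recorded; the parameters of
#' the epoch with the best checkpoint metric are retained.
#'
#' @param model A [build_frame_predictor()] result.
#' @param train_pairs,val_pairs Lists of pairs from [build_subsequences()].
#' @param tcfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return The model with trained parameters and a `training` element
#'   (`history` data frame, `selected_epoch`, `best_metric`).
#' @export
train_predictor <- function(model, train_pairs, val_pairs, tcfg,
                            verbose = FALSE) {
  stopifnot(inherits(model, "frame_predictor"), inherits(tcfg, "train_config"))
  if (!length(train_pairs) || !length(val_pairs)) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  ccfg <- fp_cpp_cfg(model$mcfg)
  H <- ccfg$H; W <- ccfg$W; nh4 <- model$mcfg$filters[4]
  rate <- model$mcfg$dropout_rate
  par <- model$par
  st <- adam_init(length(par))
  hist <- vector("list", tcfg$epochs)
  best <- NULL

  with_local_seed(tcfg$rng_seed, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(length(train_pairs))
      if (!is.null(tcfg$steps_per_epoch)) {
        ord <- ord[seq_len(min(tcfg$steps_per_epoch, length(ord)))]
      }
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        bidx <- ord[i:min(i + tcfg$batch_size - 1L, length(ord))]
        g <- numeric(length(par))
        bl <- 0
        for (b in bidx) {
          dm <- if (rate > 0) {
            array(stats::rbinom(H * W * nh4, 1L, 1 - rate) / (1 - rate),
                  c(H, W, nh4))
          } else NULL
          r <- fp_loss_grad(par, ccfg, train_pairs[[b]], dm)
          if (!is.finite(r$loss)) {
            stop(sprintf("non-finite loss at epoch %d (loss=%s)", ep,
                         format(r$loss)), call. = FALSE)
          }
          g <- g + r$grad
          bl <- bl + r$loss
        }
        upd <- adam_step(par, g / length(bidx), st, tcfg$learning_rate)
        par <- upd$par
        st <- upd$state
        losses <- c(losses, bl / length(bidx))
        i <- i + tcfg$batch_size
      }
      vm <- vapply(val_pairs, function(p) fp_eval_pair(par, ccfg, p),
                   numeric(3))
      row <- data.frame(epoch = ep, train_loss = mean(losses),
                        val_loss = mean(vm["loss", ]),
                        val_accuracy = mean(vm["acc", ]),
                        val_mse = mean(vm["mse", ]))
      hist[[ep]] <- row
      score <- if (tcfg$checkpoint_metric == "val_accuracy") {
        row$val_accuracy
      } else {
        -row$val_loss
      }
      if (is.null(best) || score > best$score) {
        best <- list(score = score, par = par, epoch = ep)
      }
      if (verbose) {
        message(sprintf(
          "epoch %3d  train %.5f  val %.5f  acc %.4f  mse %.6f", ep,
          row$train_loss, row$val_loss, row$val_accuracy, row$val_mse))
      }
    }
  })

  model$par <- best$par
  model$training <- list(history = do.call(rbind, hist),
                         selected_epoch = best$epoch,
                         metric = tcfg$checkpoint_metric,
                         best_metric = abs(best$score),
                         tcfg = tcfg)
  model
}

#' Predict the next frame from a window of F preprocessed frames
#'
#' Pure function of the parameters and the window (inference mode, no
#' dropout); both outputs lie strictly inside (0, 1).
#'
#' @param model A trained (or freshly built) `frame_predictor`.
#' @param window `H x W x C x F` array of consecutive preprocessed frames.
#' @return List `(full, image)`: the C-channel and 3-channel predictions.
#' @export
predict_next_frame <- function(model, window) {
  stopifnot(inherits(model, "frame_predictor"))
  is <- model$mcfg$input_shape
  d <- dim(window)
  if (length(d) != 4 || any(d != c(is["H"], is["W"], is["C"], is["F"]))) {
    stop(sprintf("window must be %d x %d x %d x %d (H x W x C x F)",
                 is["H"], is["W"], is["C"], is["F"]), call. = FALSE)
  }
  r <- cpp_fp_run(model$par, fp_cpp_cfg(model$mcfg), window, NULL, NULL, NULL,
                  FALSE)
  list(full = array(r$head1, unname(c(d[1], d[2], is["C"]))),
       image = array(r$head2, c(d[1], d[2], 3)))
}

#' One-step mean squared error of a model over pairs
#'
#' Computed on the 3-channel image head against the target's image channels.
#'
#' @param model A `frame_predictor`.
#' @param pairs Pairs from [build_subsequences()].
#' @return Mean MSE across pairs.
#' @export
one_step_mse <- function(model, pairs) {
  ccfg <- fp_cpp_cfg(model$mcfg)
  mean(vapply(pairs, function(p) fp_eval_pair(model$par, ccfg, p)["mse"],
              numeric(1)))
}

#' Persistence-baseline mean squared error
#'
#' The trivial forecaster that predicts the next frame to equal the last
#' observed frame; the floor any learned predictor must beat.
#'
#' @param pairs Pairs from [build_subsequences()].
#' @return Mean MSE of the copy-last-frame prediction (image channels).
#' @export
persistence_mse <- function(pairs) {
  mean(vapply(pairs, function(p) {
    F <- dim(p$input)[4]
    last <- p$input[, , 1:3, F]
    mean((last - p$target_image)^2)
  }, numeric(1)))
}

#' Save / load a FramePredictor checkpoint
#'
#' Writes the weights plus a JSON sidecar carrying the model and study
#' configuration, the seeds and the selected epoch, so a reloaded model
#' reproduces predictions exactly and refuses data of the wrong shape.
#'
#' @param model A `frame_predictor`.
#' @param path Checkpoint path (`.rds`; sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "frame_predictor"))
  saveRDS(model, path)
  meta <- list(class = "frame_predictor",
               model_config = model$mcfg[c("scale_preset", "filters", "kernels",
                                           "dropout_rate", "head_kernel",
                                           "activation", "study")],
               input_shape = as.list(model$mcfg$input_shape),
               n_params = length(model$par),
               init_seed = model$init_seed,
               selected_epoch = model$training$selected_epoch)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_C If given, fail unless the checkpoint's channel depth
#'   matches (e.g. loading a cleavage-study model for blastocyst data).
#' @export
load_checkpoint <- function(path, expect_C = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "frame_predictor")) {
    stop("not a FramePredictor checkpoint: ", path, call. = FALSE)
  }
  if (length(model$par) != nn_param_count(model$shapes)) {
    stop("checkpoint parameter count does not match its configuration",
         call. = FALSE)
  }
  if (!is.null(expect_C) && model$mcfg$input_shape["C"] != expect_C) {
    stop(sprintf("checkpoint has channel depth %d but %d was requested",
                 model$mcfg$input_shape["C"], expect_C), call. = FALSE)
  }
  model
}
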