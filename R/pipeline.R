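# End-to-end pipeline: simulate -> preprocess -> train predictor ->
# train cropper -> forecast -> evaluate, driven by a single run
# configuration. Every artifact directory receives a JSON sidecar with the
# config hash so results are traceable to their configuration.

`%||%` <- function(a, b) if (is.null(a)) b else a

pipe_log <- function(state, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  if (state$verbose) message(msg)
  cat(msg, "\n", file = state$logfile, append = TRUE)
}

write_sidecar <- function(dir, state, extra = list()) {
  meta <- c(list(config_hash = state$hash, rng_seed = state$seed,
                 package_version = as.character(utils::packageVersion("embryocast")),
                 created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")), extra)
  jsonlite::write_json(meta, file.path(dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the forecasting pipeline from a configuration
#'
#' Executes the requested stages (`simulate`, `preprocess`,
#' `train_predictor`, `train_cropper`, `forecast`, `evaluate`; default all)
#' and writes checkpoints, forecast frames with a provenance CSV, a metrics
#' report JSON and a structured log under `out_dir`. A stage failure aborts
#' with the stage name in the error. Reruns with the same config and seed
#' reproduce the same artifacts.
#'
#' @param cfg A `run_config` (see [read_run_config()]) or the path to its
#'   YAML file.
#' @param verbose Echo log lines to the console.
#' @return Invisibly, a list with the trained models, the forecasts, the
#'   `metrics_report` and the artifact paths.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- cfg$out_dir %||% "embryocast_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(hash = config_hash(cfg), seed = cfg$rng_seed %||% 1L,
                verbose = verbose,
                logfile = file.path(out_dir, "run.log"))
  cat("", file = state$logfile)
  write_sidecar(out_dir, state, list(study = cfg$study %||% "cells_stage"))
  stages <- cfg$stages %||% c("simulate", "preprocess", "train_predictor",
                              "train_cropper", "forecast", "evaluate")
  res <- list(paths = list(out_dir = out_dir), config_hash = state$hash)
  stage <- function(name, code) {
    if (!name %in% stages) return(invisible(NULL))
    pipe_log(state, "stage %s: start", name)
    tryCatch(code, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  study <- cfg$study %||% "cells_stage"
  category <- cfg$category %||% "transfer"
  seed <- as.integer(state$seed)

  ## simulate ---------------------------------------------------------------
  videos <- NULL
  stage("simulate", {
    sc <- cfg$simulate %||% list()
    simc <- sim_config(study = study, category = category,
                       frames_per_hour = sc$frames_per_hour %||% NULL,
                       image_size = sc$image_size %||% 250L,
                       rng_seed = seed,
                       fragmentation_rate = sc$fragmentation_rate %||% 0.05,
                       n_videos = sc$n_videos %||% 8L)
    videos <- simulate_videos(simc, with_masks = TRUE)
    data_dir <- file.path(out_dir, "data")
    write_dataset(videos, data_dir)
    write_sidecar(data_dir, state)
    res$paths$data <- data_dir
    pipe_log(state, "simulated %d %s/%s videos (%d frames each)",
             length(videos), study, category, length(videos[[1]]$frames))
  })

  ## preprocess -------------------------------------------------------------
  pv <- NULL; scfg <- NULL; split <- NULL
  stage("preprocess", {
    if (is.null(videos)) {
      manifest <- read_manifest(file.path(out_dir, "data"))
      videos <- lapply(manifest$video_id, function(id) {
        read_video(file.path(out_dir, "data", id))
      })
      names(videos) <- manifest$video_id
    }
    pp <- cfg$preprocess %||% list()
    scfg <- study_config(study, F = pp$F %||% 7L, H = pp$H %||% 128L,
                          W = pp$W %||% 128L)
    pv <- lapply(videos, preprocess_video, cfg = scfg)
    n_eval <- (cfg$split %||% list())$n_eval %||% 2L
    ids <- names(pv)
    eval_ids <- tail(ids, n_eval)
    sp <- split_train_val(setdiff(ids, eval_ids),
                          (cfg$split %||% list())$ratio %||% 0.8,
                          seed = seed)
    split <- list(train = sp$train, val = sp$val, eval = eval_ids)
    pipe_log(state, "preprocessed %d videos to %dx%dx%d; split %d/%d/%d",
             length(pv), scfg$H, scfg$W, scfg$C, length(sp$train),
             length(sp$val), length(eval_ids))
  })

  ## train the frame predictor ----------------------------------------------
  model <- NULL
  stage("train_predictor", {
    pc <- cfg$predictor %||% list()
    mcfg <- model_config(scfg, scale_preset = pc$scale_preset %||% "tiny")
    model <- build_frame_predictor(mcfg, seed = seed)
    pairs_of <- function(ids) {
      do.call(c, lapply(ids, function(id) {
        build_subsequences(pv[[id]], video_id = id)
      }))
    }
    tcfg <- train_config(epochs = pc$epochs %||% 2L,
                         batch_size = pc$batch_size %||% 2L,
                         learning_rate = pc$learning_rate %||% 2e-3,
                         rng_seed = seed,
                         steps_per_epoch = pc$steps_per_epoch %||% NULL)
    val_pairs <- pairs_of(split$val)
    nval <- pc$max_val_pairs %||% 16L
    if (length(val_pairs) > nval) {
      val_pairs <- with_local_seed(seed, sample(val_pairs, nval))
    }
    model <- train_predictor(model, pairs_of(split$train), val_pairs, tcfg)
    ck <- file.path(out_dir, "predictor.rds")
    save_checkpoint(model, ck)
    res$paths$predictor <- ck
    pipe_log(state, "trained predictor: %d epochs, best %s %.4f",
             tcfg$epochs, tcfg$checkpoint_metric, model$training$best_metric)
  })

  ## train the embryo cropper ------------------------------------------------
  cropper <- NULL
  stage("train_cropper", {
    cc <- cfg$cropper %||% list()
    n_img <- cc$n_images %||% 40L
    # frames sampled across videos and stages, masks from the renderer
    take <- with_local_seed(seed + 1L, {
      lapply(seq_len(n_img), function(i) {
        v <- sample(length(videos), 1)
        f <- sample(length(videos[[v]]$frames), 1)
        list(v = v, f = f)
      })
    })
    imgs <- lapply(take, function(tk) {
      resize_and_normalize(videos[[tk$v]]$frames[[tk$f]], scfg$H, scfg$W)
    })
    msks <- lapply(take, function(tk) {
      m <- videos[[tk$v]]$masks[[tk$f]]
      if (is.null(m)) stop("dataset has no masks; simulate with masks")
      mm <- EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                               w = scfg$H, h = scfg$W,
                                               filter = "bilinear"))
      (mm > 0.5) * 1L
    })
    groups <- vapply(take, function(tk) as.character(tk$v), character(1))
    cropper <- build_unet(c(scfg$H, scfg$W, 3L), n_classes = 2L,
                           depth = cc$depth %||% 4L,
                           base_filters = cc$base_filters %||% 64L,
                           seed = seed)
    ccfg <- cropper_config(epochs = cc$epochs %||% 60L,
                           batch_size = cc$batch_size %||% 32L,
                           learning_rate = cc$learning_rate %||% 1e-3,
                           rng_seed = seed)
    cropper <- train_cropper(cropper, imgs, msks, ccfg, groups = groups)
    ck <- file.path(out_dir, "cropper.rds")
    saveRDS(cropper, ck)
    jsonlite::write_json(
      list(class = "unet_model", depth = cropper$depth, base = cropper$base,
           H = cropper$H, W = cropper$W, config_hash = state$hash,
           final_val_iou = tail(cropper$training$history$val_iou, 1)),
      paste0(ck, ".json"), auto_unbox = TRUE, pretty = TRUE)
    res$paths$cropper <- ck
    pipe_log(state, "trained cropper: final val IoU %.3f",
             tail(cropper$training$history$val_iou, 1))
  })

  ## forecast the evaluation videos ------------------------------------------
  forecasts <- NULL
  stage("forecast", {
    fc <- cfg$forecast %||% list()
    strategy <- fc$strategy %||% "next7"
    if (is.null(model)) model <- load_checkpoint(res$paths$predictor)
    forecasts <- lapply(split$eval, function(id) {
      frames <- pv[[id]]$frames
      hpi <- pv[[id]]$hpi
      if (strategy == "till_end") {
        forecast_till_end(model, frames, hpi)
      } else {
        forecast_next7(model, frames, hpi)
      }
    })
    names(forecasts) <- split$eval
    fdir <- file.path(out_dir, "forecast")
    dir.create(fdir, showWarnings = FALSE)
    for (id in split$eval) {
      vdir <- file.path(fdir, id)
      dir.create(vdir, showWarnings = FALSE)
      asm <- assemble_forecast_video(forecasts[[id]])
      for (nm in names(asm$frames)) {
        img <- asm$frames[[nm]][, , 1]
        png::writePNG(pmin(pmax(img, 0), 1), file.path(vdir, paste0(nm, ".png")))
      }
      write.csv(asm$provenance, file.path(vdir, "provenance.csv"),
                row.names = FALSE)
    }
    write_sidecar(fdir, state, list(strategy = strategy))
    res$paths$forecast <- fdir
    pipe_log(state, "forecast %d videos with strategy %s",
             length(forecasts), strategy)
  })

  ## evaluate -----------------------------------------------------------------
  report <- NULL
  stage("evaluate", {
    ec <- cfg$evaluate %||% list()
    truncs <- as.integer(ec$truncations %||% fvd_presets(study))
    spec <- embedder_spec(dim = ec$embedder_dim %||% 64L,
                          seed = ec$embedder_seed %||% 7L)
    if (is.null(cropper) && !is.null(res$paths$cropper)) {
      cropper <- readRDS(res$paths$cropper)
    }
    gt <- lapply(split$eval, function(id) pv[[id]]$frames)
    report <- evaluate_forecast(gt, unname(forecasts), cropper = cropper,
                                 truncations = truncs, spec = spec)
    rp <- file.path(out_dir, "metrics_report.json")
    to_json <- list(
      strategy = report$strategy, n_videos = report$n_videos,
      n_frames = report$n_frames, truncations = report$truncations,
      config_hash = state$hash,
      uncropped = list(mean_psnr = report$uncropped$mean_psnr,
                       mean_ssim = report$uncropped$mean_ssim,
                       fvd = as.list(report$uncropped$fvd)),
      cropped = if (!is.null(report$cropped)) {
        list(mean_psnr = report$cropped$mean_psnr,
             mean_ssim = report$cropped$mean_ssim,
             fvd = as.list(report$cropped$fvd))
      })
    jsonlite::write_json(to_json, rp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    write.csv(rbind(cbind(variant = "uncropped", report$uncropped$per_frame),
                    if (!is.null(report$cropped)) {
                      cbind(variant = "cropped", report$cropped$per_frame)
                    }),
              file.path(out_dir, "per_frame_metrics.csv"), row.names = FALSE)
    res$paths$report <- rp
    pipe_log(state, "evaluation: uncropped SSIM %.3f%s",
             report$uncropped$mean_ssim,
             if (!is.null(report$cropped)) {
               sprintf(", cropped SSIM %.3f", report$cropped$mean_ssim)
             } else "")
  })

  res$model <- model
  res$cropper <- cropper
  res$forecasts <- forecasts
  res$report <- report
  res$split <- split
  invisible(res)
}
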