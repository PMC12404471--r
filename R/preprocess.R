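# Preprocessing: annotated videos -> normalized multi-channel tensors and
# sliding-window (input window, next frame) training pairs.
#
# Each frame becomes an H x W x C array in [0,1]: the grayscale image
# replicated into three image channels, plus constant-valued auxiliary planes
# for normalized acquisition time and (cleavage study only) normalized cell
# count. Windows of F consecutive frames paired with the following frame are
# the unit of training and evaluation.

#' Study configuration
#'
#' Fixes tensor geometry and normalization for one study. Channel depth
#' follows the study: 5 for the cleavage-stage study (3 image + time + cell
#' count) and 4 for the blastocyst study (3 image + time; the cell-count
#' channel is dropped because compacted cells cannot be counted).
#'
#' @param study `"cells_stage"` or `"blastocyst"`.
#' @param F Input window length in frames.
#' @param H,W Spatial size after resizing.
#' @param time_window `(start_hpi, end_hpi)` used for min-max time
#'   normalization; defaults to the study window.
#' @param max_cell_count Divisor for cell-count normalization (stages are
#'   annotated up to "9+ cells").
#' @return A `study_config` list with channel depth `C` filled in.
#' @export
study_config <- function(study = c("cells_stage", "blastocyst"),
                         F = 7L, H = 128L, W = 128L,
                         time_window = NULL, max_cell_count = 9L) {
  study <- match.arg(study)
  if (is.null(time_window)) {
    time_window <- if (study == "cells_stage") c(31, 43) else c(90, 113)
  }
  if (time_window[1] >= time_window[2]) {
    stop("degenerate time window", call. = FALSE)
  }
  structure(list(study = study, F = as.integer(F), H = as.integer(H),
                 W = as.integer(W),
                 C = if (study == "cells_stage") 5L else 4L,
                 time_window = as.numeric(time_window),
                 max_cell_count = as.integer(max_cell_count)),
            class = "study_config")
}

#' Resize a grayscale frame and replicate it into three image channels
#'
#' Bilinear resize to `H` x `W`, division by 255, replication of the single
#' gray plane into three identical image channels (the predictor and the
#' cropper both consume 3-channel image stacks).
#'
#' @param frame 2-D matrix of 8-bit intensities (0--255).
#' @param H,W Target size.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
resize_and_normalize <- function(frame, H, W) {
  if (length(dim(frame)) != 2) {
    stop("frame must be a 2-D intensity matrix", call. = FALSE)
  }
  x <- frame / 255
  if (nrow(x) != H || ncol(x) != W) {
    x <- EBImage::imageData(EBImage::resize(EBImage::Image(x), w = H, h = W,
                                            filter = "bilinear"))
  }
  x <- pmin(pmax(x, 0), 1)
  array(rep(x, 3), c(H, W, 3))
}

#' Min-max normalize an acquisition time into the study window
#'
#' @param hpi Hours post insemination.
#' @param window `(start, end)` in hpi.
#' @return `(hpi - start) / (end - start)`, clipped to `[0, 1]`.
#' @export
normalize_time <- function(hpi, window) {
  if (window[1] >= window[2]) stop("degenerate time window", call. = FALSE)
  pmin(pmax((hpi - window[1]) / (window[2] - window[1]), 0), 1)
}

#' Stack auxiliary channels onto an image
#'
#' Appends constant-valued planes carrying the normalized acquisition time
#' and, for the cleavage-stage study, the normalized cell count, giving the
#' study's full channel depth (C = 5 cleavage, C = 4 blastocyst).
#'
#' @param image3 `H x W x 3` array from [resize_and_normalize()].
#' @param hpi Acquisition time (hpi).
#' @param cell_count Annotated cell count (required for the cleavage study).
#' @param cfg A [study_config()].
#' @return `H x W x C` array in `[0, 1]` with attributes `hpi` and
#'   `channel_roles`.
#' @export
stack_channels <- function(image3, hpi, cell_count = NULL, cfg) {
  stopifnot(inherits(cfg, "study_config"))
  tval <- normalize_time(hpi, cfg$time_window)
  H <- dim(image3)[1]; W <- dim(image3)[2]
  if (cfg$study == "cells_stage") {
    if (is.null(cell_count) || is.na(cell_count)) {
      stop("cell_count is required for the cells stage study", call. = FALSE)
    }
    cval <- min(max(cell_count / cfg$max_cell_count, 0), 1)
    out <- array(c(image3, rep(tval, H * W), rep(cval, H * W)), c(H, W, 5L))
    roles <- c("image", "image", "image", "time", "cell_count")
  } else {
    out <- array(c(image3, rep(tval, H * W)), c(H, W, 4L))
    roles <- c("image", "image", "image", "time")
  }
  attr(out, "hpi") <- hpi
  attr(out, "channel_roles") <- roles
  out
}

#' Preprocess a whole annotated video
#'
#' @param video An `annotated_video` (see [simulate_video()] /
#'   [read_video()]).
#' @param cfg A [study_config()].
#' @return List with `frames` (`H x W x C x N` array), `hpi`, `cell_count`,
#'   `cfg`.
#' @export
preprocess_video <- function(video, cfg) {
  stopifnot(inherits(video, "annotated_video"), inherits(cfg, "study_config"))
  ann <- video$annotations
  n <- length(video$frames)
  out <- array(0, c(cfg$H, cfg$W, cfg$C, n))
  for (i in seq_len(n)) {
    img3 <- resize_and_normalize(video$frames[[i]], cfg$H, cfg$W)
    out[, , , i] <- stack_channels(img3, ann$hpi[i], ann$cell_count[i], cfg)
  }
  list(frames = out, hpi = ann$hpi, cell_count = ann$cell_count, cfg = cfg)
}

#' Build sliding-window training pairs
#'
#' A video of N frames is reorganized into overlapping subsequences: the
#' first window holds frames x1..xF with x(F+1) as ground truth, the next
#' x2..x(F+1) with x(F+2), and so on until the last frame serves as target,
#' giving N - F pairs.
#'
#' @param pvideo A preprocessed video (see [preprocess_video()]), or an
#'   `H x W x C x N` array.
#' @param F Window length; defaults to the video's study config.
#' @param video_id Identifier carried into each pair.
#' @return List of pairs `(input, target, target_image, video_id,
#'   start_index, target_index, target_hpi)`; empty if N < F + 1.
#' @export
build_subsequences <- function(pvideo, F = NULL, video_id = "video") {
  if (is.list(pvideo)) {
    arr <- pvideo$frames
    hpi <- pvideo$hpi
    if (is.null(F)) F <- pvideo$cfg$F
  } else {
    arr <- pvideo
    hpi <- rep(NA_real_, dim(arr)[4])
  }
  stopifnot(!is.null(F), length(dim(arr)) == 4)
  n <- dim(arr)[4]
  if (n < F + 1) return(list())
  lapply(seq_len(n - F), function(s) {
    target <- arr[, , , s + F, drop = FALSE]
    dim(target) <- dim(arr)[1:3]
    list(input = arr[, , , s:(s + F - 1), drop = FALSE],
         target = target,
         target_image = target[, , 1:3, drop = FALSE],
         video_id = video_id,
         start_index = s,
         target_index = s + F,
         target_hpi = hpi[s + F])
  })
}

#' Split videos into training and validation sets
#'
#' The split is at video level (no video contributes pairs to both sides),
#' with a seeded shuffle and an 80:20 default ratio.
#'
#' @param video_ids Character vector of video identifiers (length >= 2).
#' @param ratio Training fraction, strictly inside (0, 1).
#' @param seed RNG seed for the shuffle.
#' @return List `(train, val)` of disjoint id vectors, both non-empty.
#' @export
split_train_val <- function(video_ids, ratio = 0.8, seed = 1L) {
  if (length(video_ids) < 2) stop("need at least 2 videos to split", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)", call. = FALSE)
  ids <- with_local_seed(seed, sample(video_ids))
  n_train <- min(max(round(ratio * length(ids)), 1L), length(ids) - 1L)
  list(train = sort(ids[seq_len(n_train)]),
       val = sort(ids[-seq_len(n_train)]))
}
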