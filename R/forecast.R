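# Recursive multi-hour forecasting on top of the FramePredictor.
#
# Two strategies:
#   * till_end — start from the first F real frames and roll forward to the
#     end of the study, feeding each prediction back as input; frame t's
#     horizon equals its distance from the initial real window.
#   * next7   — from every real window, recursively predict the next seven
#     frames; whenever the next real frame arrives the window advances using
#     real frames only and all seven forecasts are recomputed, superseding
#     the overlapping earlier ones and adding one new farthest frame.
#
# During recursion the full-channel (head 1) prediction is appended to the
# window. The time channel is overwritten with the true normalized
# acquisition time (the acquisition schedule is known ahead of time); the
# predicted cell-count plane is collapsed to its spatial mean so it stays a
# constant-valued channel. `feedback = "raw"` feeds head 1 back untouched.

# build the next input frame from a head-1 prediction
feedback_frame <- function(full, hpi, mcfg, feedback) {
  if (feedback == "raw") return(full)
  H <- dim(full)[1]; W <- dim(full)[2]; C <- dim(full)[3]
  full[, , 4] <- normalize_time(hpi, mcfg$time_window)
  if (C >= 5) {
    full[, , 5] <- mean(full[, , 5])
  }
  full
}

new_forecast_result <- function(entries, strategy, F, n_total,
                                partial = FALSE) {
  structure(list(entries = entries, strategy = strategy, F = F,
                 n_total = n_total, partial = partial),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  labs <- vapply(x$entries, `[[`, numeric(1), "frame_label")
  cat(sprintf("forecast_result (%s): %d entries, frame labels %s%s\n",
              x$strategy, length(x$entries),
              if (length(labs)) paste(range(labs), collapse = "..") else "-",
              if (x$partial) " [partial]" else ""))
  invisible(x)
}

forecast_entry <- function(label, pred, horizon, inputs_used) {
  list(frame_label = label, image = pred$image, full = pred$full,
       horizon = horizon, inputs_used = inputs_used)
}

#' Forecast until the end of the study
#'
#' Starting from the first `F` real frames (labels 1..F), predicts frame
#' F+1, appends the prediction to the sliding window, and repeats until
#' frame `n_total`: with a 15-frame target span the strategy forecasts
#' frames 8' through 15', using prediction 8' as input when forecasting 9'.
#' Only the first `F` frames of the result's provenance are ever real.
#'
#' @param model A trained `frame_predictor`.
#' @param frames `H x W x C x N` preprocessed real frames (N >= F).
#' @param hpi Acquisition times for labels `1..n_total` (known schedule).
#' @param n_total Last frame label to forecast.
#' @param feedback `"schedule"` (overwrite auxiliary channels, default) or
#'   `"raw"`.
#' @return A `forecast_result` with `n_total - F` entries; entry k has
#'   horizon k.
#' @export
forecast_till_end <- function(model, frames, hpi, n_total = NULL,
                              feedback = c("schedule", "raw")) {
  feedback <- match.arg(feedback)
  F <- unname(model$mcfg$input_shape["F"])
  d <- dim(frames)
  if (length(d) != 4 || d[4] < F) {
    stop(sprintf("need at least F = %d real frames", F), call. = FALSE)
  }
  if (is.null(n_total)) n_total <- length(hpi)
  if (n_total < F + 1) stop("n_total must exceed F", call. = FALSE)
  if (length(hpi) < n_total) stop("hpi must cover all forecast labels", call. = FALSE)

  n_total <- as.integer(n_total)
  window <- frames[, , , 1:F, drop = FALSE]
  window_labels <- data.frame(frame_label = 1:F, source = "real")
  entries <- vector("list", n_total - F)
  for (t in (F + 1L):n_total) {
    pred <- predict_next_frame(model, window)
    entries[[t - F]] <- forecast_entry(t, pred, horizon = t - F,
                                       inputs_used = window_labels)
    fb <- feedback_frame(pred$full, hpi[t], model$mcfg, feedback)
    window <- array(c(window[, , , 2:F], fb), dim(window))
    window_labels <- rbind(window_labels[-1, ],
                           data.frame(frame_label = t, source = "predicted"))
    rownames(window_labels) <- NULL
  }
  new_forecast_result(entries, "till_end", F, n_total)
}

#' Rolling forecast of the next seven frames
#'
#' From the real window x(t-F+1)..x(t) the strategy recursively predicts
#' x(t+1)..x(t+7) (horizons 1..7, later steps consuming earlier
#' predictions). When the next real frame arrives the window advances using
#' real frames only and all seven forecasts are recomputed: the first update
#' from x1..x7 forecasts 8'..14'; after frame 8 arrives, 9'..15'. Every
#' update yields exactly `horizon` entries unless the video ends mid-update,
#' in which case the result is flagged partial.
#'
#' @param model A trained `frame_predictor`.
#' @param frames `H x W x C x N` preprocessed real frames.
#' @param hpi Acquisition times covering labels up to `N + horizon` (times
#'   beyond the video are extrapolated from the frame spacing if missing).
#' @param horizon Number of frames forecast per update (7).
#' @param feedback As in [forecast_till_end()].
#' @return A `forecast_result` whose entries carry an `update` index; labels
#'   repeat across updates (the latest supersedes).
#' @export
forecast_next7 <- function(model, frames, hpi, horizon = 7L,
                           feedback = c("schedule", "raw")) {
  feedback <- match.arg(feedback)
  F <- unname(model$mcfg$input_shape["F"])
  d <- dim(frames)
  if (length(d) != 4 || d[4] < F) {
    stop(sprintf("need at least F = %d real frames", F), call. = FALSE)
  }
  n <- d[4]
  # extend the known acquisition schedule past the last real frame
  if (length(hpi) < n + horizon) {
    step <- if (length(hpi) >= 2) hpi[2] - hpi[1] else 1
    hpi <- c(hpi, hpi[length(hpi)] + step * seq_len(n + horizon - length(hpi)))
  }
  horizon <- as.integer(horizon)
  last_starts <- F:max(F, as.integer(n) - horizon)
  partial <- n < F + horizon
  entries <- list()
  upd <- 0L
  for (t in last_starts) {
    upd <- upd + 1L
    window <- frames[, , , (t - F + 1):t, drop = FALSE]
    window_labels <- data.frame(frame_label = (t - F + 1):t, source = "real")
    for (h in seq_len(horizon)) {
      label <- t + h
      pred <- predict_next_frame(model, window)
      e <- forecast_entry(label, pred, horizon = h,
                          inputs_used = window_labels)
      e$update <- upd
      entries[[length(entries) + 1L]] <- e
      fb <- feedback_frame(pred$full, hpi[label], model$mcfg, feedback)
      window <- array(c(window[, , , 2:F], fb), dim(window))
      window_labels <- rbind(window_labels[-1, ],
                             data.frame(frame_label = label,
                                        source = "predicted"))
      rownames(window_labels) <- NULL
    }
  }
  new_forecast_result(entries, "next7", F, n, partial = partial)
}

#' Assemble a forecast video from a forecast result
#'
#' `policy = "latest"` keeps the most recently updated prediction per frame
#' label; `policy = "by_horizon"` keeps predictions made exactly `h` steps
#' ahead. For the till-end strategy every label is predicted once and the
#' policy has no effect.
#'
#' @param result A `forecast_result`.
#' @param policy `"latest"` or `"by_horizon"`.
#' @param h Horizon for `policy = "by_horizon"` (1..7 for next7).
#' @return List with `frames` (named list of `H x W x 3` images keyed by
#'   frame label) and `provenance` (data frame `frame_label`, `horizon`,
#'   `strategy`, `update`).
#' @export
assemble_forecast_video <- function(result, policy = c("latest", "by_horizon"),
                                    h = 1L) {
  stopifnot(inherits(result, "forecast_result"))
  policy <- match.arg(policy)
  if (!length(result$entries)) stop("empty forecast result", call. = FALSE)
  ent <- result$entries
  if (policy == "by_horizon") {
    maxh <- max(vapply(ent, `[[`, numeric(1), "horizon"))
    if (h > maxh) {
      stop(sprintf("no predictions at horizon %d (max %d)", h, maxh),
           call. = FALSE)
    }
    ent <- Filter(function(e) e$horizon == h, ent)
  }
  labs <- vapply(ent, `[[`, numeric(1), "frame_label")
  keep <- rev(!duplicated(rev(labs)))  # last occurrence per label wins
  ent <- ent[keep]
  labs <- labs[keep]
  ord <- order(labs)
  ent <- ent[ord]; labs <- labs[ord]
  frames <- lapply(ent, `[[`, "image")
  names(frames) <- sprintf("frame_%04d", labs)
  prov <- data.frame(frame_label = labs,
                     horizon = vapply(ent, `[[`, numeric(1), "horizon"),
                     strategy = result$strategy,
                     update = vapply(ent, function(e) {
                       if (is.null(e$update)) NA_integer_ else e$update
                     }, integer(1)))
  list(frames = frames, provenance = prov)
}

#' Provenance table of a forecast result
#'
#' One row per (entry, window slot): which frame labels fed each prediction
#' and whether each was a real or a predicted frame. This is the table the
#' strategy bookkeeping tests compare against hand enumeration.
#'
#' @param result A `forecast_result`.
#' @return Data frame `frame_label`, `horizon`, `update`, `input_label`,
#'   `input_source`.
#' @export
forecast_provenance <- function(result) {
  stopifnot(inherits(result, "forecast_result"))
  do.call(rbind, lapply(result$entries, function(e) {
    data.frame(frame_label = e$frame_label, horizon = e$horizon,
               update = if (is.null(e$update)) NA_integer_ else e$update,
               input_label = e$inputs_used$frame_label,
               input_source = e$inputs_used$source)
  }))
}
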