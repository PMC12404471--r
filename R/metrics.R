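# Video-quality evaluation: per-frame PSNR and SSIM, and a Fréchet video
# distance (FVD-style) over truncated sequences with a pluggable,
# deterministic sequence embedder. Metrics are always computed on 3-channel
# image predictions (head 2); with a cropper, a second "embryo-only" variant
# mattes the ground-truth-derived mask onto both sides first.

#' Peak signal-to-noise ratio
#'
#' `10 log10(1 / MSE)` for images in `[0, 1]`. Identical images have zero
#' error, which is undefined in dB, so the value is capped.
#'
#' @param reference,test Arrays of identical shape with values in `[0, 1]`.
#' @param cap Value returned when MSE = 0 (and upper bound otherwise).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, cap = 100) {
  if (!all(dim(reference) == dim(test))) {
    stop("shape mismatch between reference and test", call. = FALSE)
  }
  mse <- mean((reference - test)^2)
  if (mse == 0) return(cap)
  min(10 * log10(1 / mse), cap)
}

#' Structural similarity index
#'
#' Standard SSIM with a Gaussian weighting window (sigma = 1.5, 11 x 11
#' taps), constants K1 = 0.01 and K2 = 0.03 at data range 1, local means and
#' variances from Gaussian filtering with replicate edges, and the mean map
#' cropped by the window radius; multi-channel images are averaged over
#' channels.
#'
#' @param reference,test Matrices or `H x W x C` arrays in `[0, 1]`.
#' @param sigma Gaussian window standard deviation.
#' @param K1,K2 Stabilization constants.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(reference, test, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  if (!all(dim(reference) == dim(test))) {
    stop("shape mismatch between reference and test", call. = FALSE)
  }
  radius <- as.integer(3.5 * sigma + 0.5)
  if (length(dim(reference)) == 3) {
    return(mean(vapply(seq_len(dim(reference)[3]), function(ch) {
      ssim(reference[, , ch], test[, , ch], sigma, K1, K2)
    }, numeric(1))))
  }
  if (min(dim(reference)) < 2 * radius + 1) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  C1 <- K1^2
  C2 <- K2^2
  f <- function(m) cpp_gauss_blur(m, sigma, radius)
  mu1 <- f(reference); mu2 <- f(test)
  # plain Gaussian-weighted moments (the Wang et al. convention)
  s11 <- f(reference * reference) - mu1 * mu1
  s22 <- f(test * test) - mu2 * mu2
  s12 <- f(reference * test) - mu1 * mu2
  S <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
       ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  H <- nrow(S); W <- ncol(S)
  mean(S[(radius + 1):(H - radius), (radius + 1):(W - radius)])
}

#' Sequence embedder specification
#'
#' The Fréchet video distance requires a spatio-temporal feature extractor.
#' In place of a pretrained video network this package ships a seeded
#' deterministic default: frames are reduced to grayscale, bilinearly
#' downsampled, temporally differenced, convolved with a fixed random bank
#' of 3-D filters, ReLU-rectified and pooled into per-filter statistics,
#' then projected to `dim` features with a seeded random matrix. The
#' embedder is fixed by `(name, dim, seed)`, so scores are reproducible; a
#' custom function can be supplied to drop in an external pretrained
#' embedder. Absolute scores depend on the embedder and are only comparable
#' within one embedder spec.
#'
#' @param name Embedder name (`"diff3d"` for the built-in default).
#' @param dim Feature dimension.
#' @param seed Seed fixing the random filter bank and projection.
#' @param fn Optional custom embedder `function(frames_array) -> numeric`.
#' @return An `embedder_spec`.
#' @export
embedder_spec <- function(name = "diff3d", dim = 64L, seed = 7L, fn = NULL) {
  structure(list(name = name, dim = as.integer(dim), seed = as.integer(seed),
                 fn = fn),
            class = "embedder_spec")
}

# frames: H x W x 3 x T array or list of H x W x 3 arrays
as_frames_array <- function(frames) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    out <- array(0, c(d[1], d[2], if (length(d) == 3) d[3] else 1, length(frames)))
    for (i in seq_along(frames)) out[, , , i] <- frames[[i]]
    out
  } else if (length(dim(frames)) == 4) {
    frames
  } else {
    stop("frames must be a list of arrays or an H x W x C x T array",
         call. = FALSE)
  }
}

#' Embed a frame sequence into a fixed-length feature vector
#'
#' @param frames `H x W x 3 x T` array (or list of frames), T >= 2.
#' @param spec An [embedder_spec()].
#' @return Numeric feature vector of length `spec$dim`.
#' @export
embed_sequence <- function(frames, spec = embedder_spec()) {
  stopifnot(inherits(spec, "embedder_spec"))
  arr <- as_frames_array(frames)
  T <- dim(arr)[4]
  if (T < 2) stop("need at least 2 frames to embed a sequence", call. = FALSE)
  if (!is.null(spec$fn)) return(spec$fn(arr))

  side <- 16L
  gs <- array(0, c(side, side, T))
  for (t in seq_len(T)) {
    g <- apply(arr[, , , t, drop = FALSE][, , , 1], c(1, 2), mean)
    gs[, , t] <- EBImage::imageData(EBImage::resize(EBImage::Image(g),
                                                    w = side, h = side,
                                                    filter = "bilinear"))
  }
  dif <- gs[, , -1, drop = FALSE] - gs[, , -T, drop = FALSE]
  Td <- dim(dif)[3]

  nf <- 8L
  bank <- with_local_seed(spec$seed, {
    list(w = array(rnorm(nf * 27) / sqrt(27), c(3, 3, 3, nf)),
         proj = matrix(rnorm((4 * nf + 6) * spec$dim) / sqrt(4 * nf + 6),
                       4 * nf + 6, spec$dim))
  })

  feats <- numeric(0)
  if (Td >= 3) {
    oH <- side - 2L; oW <- side - 2L; oT <- Td - 2L
    for (k in seq_len(nf)) {
      acc <- array(0, c(oH, oW, oT))
      for (a in 0:2) for (b in 0:2) for (cc in 0:2) {
        acc <- acc + bank$w[a + 1, b + 1, cc + 1, k] *
          dif[(1 + a):(oH + a), (1 + b):(oW + b), (1 + cc):(oT + cc)]
      }
      acc <- pmax(acc, 0)
      feats <- c(feats, mean(acc), stats::sd(acc),
                 mean(apply(acc, 3, max)), mean(acc > 0))
    }
  } else {
    feats <- numeric(4 * nf)
  }
  glob <- c(mean(gs), stats::sd(gs), mean(abs(dif)), stats::sd(dif),
            mean(gs[, , 1]), mean(gs[, , T]))
  feat_in <- c(feats, glob)
  feat_in[!is.finite(feat_in)] <- 0
  as.numeric(feat_in %*% bank$proj)
}

# symmetric PSD square root via eigendecomposition (negative eigenvalues
# from numerical noise are clamped at zero)
sqrtm_sym <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Fréchet distance between two Gaussians
#'
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^(1/2))`, computed with the
#' symmetrized matrix square root `(S1^(1/2) S2 S1^(1/2))^(1/2)` and
#' clamped at zero against numerical noise.
#'
#' @param mu1,mu2 Mean vectors.
#' @param cov1,cov2 Covariance matrices (symmetric PSD).
#' @return Non-negative scalar; 0 iff the moments coincide.
#' @export
frechet_distance <- function(mu1, cov1, mu2, cov2) {
  if (length(mu1) != length(mu2) || !all(dim(cov1) == dim(cov2))) {
    stop("dimension mismatch between the two Gaussians", call. = FALSE)
  }
  cov1 <- as.matrix(cov1); cov2 <- as.matrix(cov2)
  s1h <- sqrtm_sym(cov1)
  cross <- sqrtm_sym(s1h %*% cov2 %*% s1h)
  val <- sum((mu1 - mu2)^2) + sum(diag(cov1)) + sum(diag(cov2)) -
    2 * sum(diag(cross))
  max(val, 0)
}

#' Truncation-length presets for the FVD evaluation
#'
#' Cleavage-stage sequences are scored at 10, 14 and 28 frames (about 2-3,
#' 4-5 and 7-10 hours at the study frame rates); blastocyst sequences at 60,
#' 120 and 180 frames (8, 15 and 22 hours).
#'
#' @param study `"cells_stage"` or `"blastocyst"`.
#' @return Integer vector of truncation lengths.
#' @export
fvd_presets <- function(study = c("cells_stage", "blastocyst")) {
  study <- match.arg(study)
  if (study == "cells_stage") c(10L, 14L, 28L) else c(60L, 120L, 180L)
}

#' Fréchet video distance over sets of sequences
#'
#' Truncates every sequence to its first `truncate_at` frames, embeds each
#' with the (deterministic) embedder, fits Gaussian moments per side and
#' returns their Fréchet distance. Sequences shorter than the truncation are
#' skipped with a warning; each side needs at least 2 surviving sequences. A
#' small diagonal jitter regularizes the covariances.
#'
#' @param real_seqs,pred_seqs Lists of sequences (each `H x W x 3 x T` array
#'   or list of frames).
#' @param truncate_at Truncation length in frames.
#' @param spec An [embedder_spec()].
#' @param jitter Diagonal regularization added to both covariances.
#' @return Non-negative FVD score (identical sets give 0 up to numerics).
#' @export
fvd_score <- function(real_seqs, pred_seqs, truncate_at,
                      spec = embedder_spec(), jitter = 1e-10) {
  trunc1 <- function(seqs) {
    out <- list()
    for (s in seqs) {
      arr <- as_frames_array(s)
      if (dim(arr)[4] < truncate_at) {
        warning(sprintf("skipping a sequence shorter than %d frames",
                        truncate_at), call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- arr[, , , seq_len(truncate_at), drop = FALSE]
    }
    out
  }
  r <- trunc1(real_seqs)
  p <- trunc1(pred_seqs)
  if (length(r) < 2 || length(p) < 2) {
    stop("need at least 2 sequences per side after truncation", call. = FALSE)
  }
  er <- t(vapply(r, embed_sequence, numeric(spec$dim), spec = spec))
  ep <- t(vapply(p, embed_sequence, numeric(spec$dim), spec = spec))
  reg <- diag(jitter, spec$dim)
  frechet_distance(colMeans(er), stats::cov(er) + reg,
                   colMeans(ep), stats::cov(ep) + reg)
}

#' Evaluate forecasts against ground truth
#'
#' Computes per-frame PSNR and SSIM (averaged over all forecast frames,
#' image channels only) and the FVD at each truncation length, with and —
#' when a cropper is supplied — without background: the mask predicted from
#' each ground-truth frame is matted onto both the ground-truth and the
#' forecast frame before scoring. For the FVD each evaluated video
#' contributes one sequence per side (its first `truncate_at` forecast
#' frames and the matching ground truth), so at least two videos are needed
#' for a score; shorter videos are skipped at that truncation.
#'
#' @param gt_frames One `H x W x C x N` array of preprocessed ground-truth
#'   frames, or a list of them (one per video).
#' @param forecast A `forecast_result`, or a list matching `gt_frames`.
#' @param cropper Optional trained `unet_model`.
#' @param truncations Integer truncation lengths for the FVD (default: the
#'   study presets inferred from the channel depth).
#' @param spec An [embedder_spec()].
#' @param policy Frame-selection policy for multi-update forecasts.
#' @param feather Matte feather radius in pixels.
#' @return A `metrics_report`: list with `uncropped` / `cropped` blocks
#'   (`mean_psnr`, `mean_ssim`, `fvd` named by truncation, `per_frame`) and
#'   evaluation counts.
#' @export
evaluate_forecast <- function(gt_frames, forecast, cropper = NULL,
                              truncations = NULL, spec = embedder_spec(),
                              policy = "latest", feather = 0) {
  if (inherits(forecast, "forecast_result")) forecast <- list(forecast)
  if (!is.list(gt_frames) || !is.null(dim(gt_frames))) gt_frames <- list(gt_frames)
  stopifnot(length(gt_frames) == length(forecast))
  if (is.null(truncations)) {
    truncations <- fvd_presets(
      if (dim(gt_frames[[1]])[3] >= 5) "cells_stage" else "blastocyst")
  }

  # per video: aligned (gt, prediction, mask) frame lists
  per_video <- lapply(seq_along(forecast), function(i) {
    fc <- forecast[[i]]
    stopifnot(inherits(fc, "forecast_result"))
    asm <- assemble_forecast_video(fc, policy = policy)
    labs <- asm$provenance$frame_label
    n_gt <- dim(gt_frames[[i]])[4]
    keep <- labs <= n_gt
    if (!any(keep)) stop("no overlap between forecast labels and video frames",
                         call. = FALSE)
    labs <- labs[keep]
    gt <- lapply(labs, function(l) gt_frames[[i]][, , 1:3, l])
    preds <- asm$frames[keep]
    masks <- if (!is.null(cropper)) lapply(gt, predict_mask, model = cropper)
    list(video = i, labs = labs, gt = gt, preds = preds, masks = masks)
  })

  score_side <- function(cropped) {
    rows <- list(); gseq <- list(); pseq <- list()
    for (pv in per_video) {
      gt <- pv$gt; pr <- pv$preds
      if (cropped) {
        gt <- mapply(function(g, m) apply_matte(m, g, feather), gt, pv$masks,
                     SIMPLIFY = FALSE)
        pr <- mapply(function(p, m) apply_matte(m, p, feather), pr, pv$masks,
                     SIMPLIFY = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        video = pv$video, frame_label = pv$labs,
        psnr = mapply(psnr, gt, pr), ssim = mapply(ssim, gt, pr))
      gseq[[length(gseq) + 1L]] <- gt
      pseq[[length(pseq) + 1L]] <- pr
    }
    per_frame <- do.call(rbind, rows)
    fvd <- sapply(truncations, function(tr) {
      ok <- vapply(gseq, function(g) length(g) >= tr, logical(1))
      if (sum(ok) < 2) return(NA_real_)
      fvd_score(lapply(gseq[ok], function(g) g[1:tr]),
                lapply(pseq[ok], function(p) p[1:tr]),
                truncate_at = tr, spec = spec)
    })
    names(fvd) <- paste0("t", truncations)
    list(per_frame = per_frame, mean_psnr = mean(per_frame$psnr),
         mean_ssim = mean(per_frame$ssim), fvd = fvd)
  }

  report <- list(
    strategy = forecast[[1]]$strategy,
    n_videos = length(per_video),
    n_frames = sum(vapply(per_video, function(pv) length(pv$labs), numeric(1))),
    truncations = truncations,
    uncropped = score_side(FALSE)
  )
  if (!is.null(cropper)) report$cropped <- score_side(TRUE)
  structure(report, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (%s strategy, %d frames)\n", x$strategy,
              x$n_frames))
  show <- function(side, nm) {
    if (is.null(side)) return()
    cat(sprintf("  %-9s PSNR %6.2f dB  SSIM %6.4f  FVD %s\n", nm,
                side$mean_psnr, side$mean_ssim,
                paste(sprintf("%s=%.1f", names(side$fvd), side$fvd),
                      collapse = " ")))
  }
  show(x$uncropped, "uncropped")
  show(x$cropped, "cropped")
  invisible(x)
}
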