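# Embryo cropper: a vanilla U-Net that segments the embryo (cell mass plus
# zona pellucida) from the microwell background, and binary matting of the
# resulting mask onto ground-truth and predicted frames so quality metrics
# can be computed on the embryo region only.

#' Cropper training configuration
#'
#' Full-scale defaults follow the segmentation training protocol: 60 epochs,
#' batch size 32, Adam at 1e-3, sparse categorical cross entropy, horizontal
#' and vertical flip augmentation, 80:20 split.
#'
#' @param epochs,batch_size,learning_rate Optimization settings.
#' @param flip_horizontal,flip_vertical Augmentation switches (flips are
#'   applied identically to image and mask).
#' @param split Training fraction of the image set.
#' @param rng_seed Seed for the split, shuffling and flips.
#' @return A `cropper_config` list.
#' @export
cropper_config <- function(epochs = 60L, batch_size = 32L,
                           learning_rate = 1e-3, flip_horizontal = TRUE,
                           flip_vertical = TRUE, split = 0.8, rng_seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            split > 0, split < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 flip_horizontal = flip_horizontal,
                 flip_vertical = flip_vertical,
                 split = split, rng_seed = as.integer(rng_seed)),
            class = "cropper_config")
}

unet_cpp_cfg <- function(model) {
  list(H = model$H, W = model$W, Cin = model$Cin, depth = model$depth,
       base = model$base, nclasses = model$n_classes,
       precision = model$precision %||% "double")
}

#' Build a U-Net segmentation model
#'
#' Standard encoder--decoder with skip connections: `depth` levels of two
#' 3x3 ReLU convolutions + 2x2 max pooling, a bottleneck, nearest-neighbor
#' up-sampling with halving convolutions and skip concatenation on the way
#' up, and a 1x1 softmax head over `n_classes` per-pixel classes. Trained
#' with sparse categorical cross entropy.
#'
#' @param input_shape `(H, W, 3)`; H and W must be divisible by `2^depth`
#'   (16 for the default 4-level net).
#' @param n_classes Number of per-pixel classes (2: embryo / background).
#' @param depth Number of pooling levels.
#' @param base_filters Filters in the first encoder block (doubling per
#'   level; 64 reproduces the full-scale net, smaller values give the tiny
#'   variant used in the tests).
#' @param seed Weight-initialization seed.
#' @param precision `"single"` (training throughput) or `"double"`.
#' @return A `unet_model` object.
#' @export
build_unet <- function(input_shape, n_classes = 2L, depth = 4L,
                       base_filters = 64L, seed = 1L,
                       precision = c("single", "double")) {
  precision <- match.arg(precision)
  stopifnot(length(input_shape) == 3)
  H <- as.integer(input_shape[1]); W <- as.integer(input_shape[2])
  Cin <- as.integer(input_shape[3])
  if (H %% 2^depth != 0 || W %% 2^depth != 0) {
    stop(sprintf("spatial size must be divisible by %d for depth %d",
                 2^depth, depth), call. = FALSE)
  }
  model <- structure(list(H = H, W = W, Cin = Cin,
                          n_classes = as.integer(n_classes),
                          depth = as.integer(depth),
                          base = as.integer(base_filters),
                          precision = precision,
                          init_seed = as.integer(seed), training = NULL),
                     class = "unet_model")
  shapes <- lapply(cpp_unet_shapes(unet_cpp_cfg(model)),
                   function(d) c(d[1], d[2]))
  model$shapes <- shapes
  model$par <- nn_init_params(shapes, seed)
  model
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("U-Net cropper: %d x %d x %d, depth %d, base %d, %s parameters\n",
              x$H, x$W, x$Cin, x$depth, x$base,
              format(length(x$par), big.mark = ",")))
  invisible(x)
}

flip_pair <- function(img, mask, fh, fv) {
  if (fh) {
    img <- img[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask)))]
  }
  if (fv) {
    img <- img[rev(seq_len(nrow(mask))), , , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), ]
  }
  list(img = img, mask = mask)
}

#' Intersection-over-union of two binary masks
#' @param a,b Binary matrices of equal size.
#' @return IoU in `[0, 1]` (1 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  a <- a > 0.5; b <- b > 0.5
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Train the embryo cropper
#'
#' @param model A [build_unet()] result.
#' @param images List of `H x W x 3` arrays in `[0, 1]`.
#' @param masks List of matching binary mask matrices (1 = embryo).
#' @param cfg A [cropper_config()].
#' @param groups Optional grouping vector (e.g. source video ids); the
#'   train/validation split then separates whole groups.
#' @param verbose Print one line per epoch.
#' @return The model with trained parameters and a `training` history
#'   (per-epoch loss and validation IoU).
#' @export
train_cropper <- function(model, images, masks, cfg = cropper_config(),
                          groups = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "cropper_config"))
  if (length(images) != length(masks)) {
    stop("images and masks must be paired 1:1", call. = FALSE)
  }
  n <- length(images)
  if (is.null(groups)) groups <- as.character(seq_len(n))
  gids <- unique(groups)
  sp <- if (length(gids) >= 2) {
    split_train_val(gids, cfg$split, seed = cfg$rng_seed)
  } else {
    list(train = gids, val = gids)
  }
  tr_idx <- which(groups %in% sp$train)
  va_idx <- which(groups %in% sp$val)

  ccfg <- unet_cpp_cfg(model)
  par <- model$par
  st <- adam_init(length(par))
  hist <- vector("list", cfg$epochs)

  with_local_seed(cfg$rng_seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        bidx <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
        g <- numeric(length(par))
        bl <- 0
        for (b in bidx) {
          fh <- cfg$flip_horizontal && runif(1) < 0.5
          fv <- cfg$flip_vertical && runif(1) < 0.5
          fp <- flip_pair(images[[b]], masks[[b]], fh, fv)
          lab <- matrix(as.integer(fp$mask > 0.5), model$H, model$W)
          r <- cpp_unet_run(par, ccfg, fp$img, lab, TRUE)
          if (!is.finite(r$loss)) {
            stop(sprintf("non-finite loss at epoch %d", ep), call. = FALSE)
          }
          g <- g + r$grad
          bl <- bl + r$loss
        }
        upd <- adam_step(par, g / length(bidx), st, cfg$learning_rate)
        par <- upd$par
        st <- upd$state
        losses <- c(losses, bl / length(bidx))
        i <- i + cfg$batch_size
      }
      vio <- vapply(va_idx, function(b) {
        pm <- unet_probs(par, ccfg, images[[b]])
        mask_iou(pm[, , 2] > 0.5, masks[[b]])
      }, numeric(1))
      hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                               val_iou = mean(vio))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f  val IoU %.4f", ep,
                        mean(losses), mean(vio)))
      }
    }
  })

  model$par <- par
  model$training <- list(history = do.call(rbind, hist),
                         split = sp, cfg = cfg)
  model
}

unet_probs <- function(par, ccfg, img) {
  r <- cpp_unet_run(par, ccfg, img, NULL, FALSE)
  array(r$probs, c(ccfg$H, ccfg$W, ccfg$nclasses))
}

#' Predict the embryo mask of a frame
#'
#' Per-pixel argmax over the class scores, post-processed to the single
#' largest connected embryo component (one embryo per microwell, so any
#' additional specks are noise).
#'
#' @param model A trained `unet_model`.
#' @param frame `H x W x 3` array in `[0, 1]` (a 2-D matrix is replicated).
#' @param largest_component Keep only the largest connected component.
#' @return A `segmentation_mask`: binary matrix with attribute `probs`.
#' @export
predict_mask <- function(model, frame, largest_component = TRUE) {
  stopifnot(inherits(model, "unet_model"))
  if (length(dim(frame)) == 2) frame <- array(rep(frame, 3), c(dim(frame), 3))
  if (!all(dim(frame) == c(model$H, model$W, model$Cin))) {
    stop(sprintf("frame must be %d x %d x %d", model$H, model$W, model$Cin),
         call. = FALSE)
  }
  probs <- unet_probs(model$par, unet_cpp_cfg(model), frame)
  mask <- (probs[, , 2] > probs[, , 1]) * 1L
  if (largest_component && any(mask > 0)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
    tab <- tabulate(lab[lab > 0])
    mask <- (lab == which.max(tab)) * 1L
  }
  structure(matrix(as.integer(mask), model$H, model$W),
            probs = probs, class = c("segmentation_mask", class(mask)))
}

#' Matte a mask onto a frame
#'
#' Sets the background to zero, optionally feathering the mask boundary with
#' a Gaussian alpha ramp. For evaluation the mask derived from a
#' ground-truth frame is applied both to that frame and to its paired
#' prediction.
#'
#' @param mask Binary matrix (e.g. from [predict_mask()]).
#' @param frame `H x W x 3` array (or 2-D matrix).
#' @param feather Gaussian feather radius in pixels (0 = hard matte).
#' @return The matted frame, same shape as `frame`.
#' @export
apply_matte <- function(mask, frame, feather = 0) {
  m2 <- if (length(dim(frame)) == 2) frame else frame[, , 1]
  if (!all(dim(m2) == dim(mask))) {
    stop("mask and frame sizes differ", call. = FALSE)
  }
  alpha <- matrix(as.numeric(mask > 0.5), nrow(mask), ncol(mask))
  if (feather > 0) {
    alpha <- cpp_gauss_blur(alpha, feather, ceiling(3 * feather))
    alpha <- pmin(pmax(alpha, 0), 1)
  }
  if (length(dim(frame)) == 2) {
    frame * alpha
  } else {
    out <- frame
    for (ch in seq_len(dim(frame)[3])) out[, , ch] <- frame[, , ch] * alpha
    out
  }
}
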