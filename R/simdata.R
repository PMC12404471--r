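# Synthetic time-lapse embryo video simulator.
#
# Generates annotated grayscale videos that mimic the structure of clinical
# time-lapse incubator recordings: a circular embryo surrounded by a zona
# pellucida ring, sitting in a microwell, dividing on a morphokinetic
# schedule. Two developmental windows are covered (day-2 cleavage stages and
# day-4 compaction-to-blastocyst) and two trajectory profiles ("transfer" =
# timely divisions, "avoid" = delayed or arrested development, more
# fragmentation). All randomness is derived from the config seed so identical
# configs give byte-identical videos.

STAGE_LEVELS <- c("2cell", "3cell", "4cell", "5to8cell", "9plus",
                  "compaction", "morula", "blastocyst_start", "blastocyst_full")

STAGE_CELLS <- c("2cell" = 2, "3cell" = 3, "4cell" = 4, "5to8cell" = 6,
                 "9plus" = 9, "compaction" = 12, "morula" = 12,
                 "blastocyst_start" = 12, "blastocyst_full" = 12)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic embryo video generator. Defaults
#' reproduce the acquisition conditions of clinical time-lapse incubators:
#' day-2 cleavage recordings span 31--43 hours post insemination (hpi) and
#' day-4 blastocyst recordings span 90--113 hpi; frame rates are 3, 4 or 8
#' frames per hour; source frames are 8-bit and square.
#'
#' @param study `"cells_stage"` (day-2 cleavage window) or `"blastocyst"`
#'   (day-4 compaction-to-blastocyst window).
#' @param category `"transfer"` (timely development) or `"avoid"` (delayed or
#'   arrested development with heavier fragmentation).
#' @param frames_per_hour Acquisition rate; one of 3, 4 or 8. Defaults to 4
#'   for the cleavage study and 8 for the blastocyst study.
#' @param window Length-2 numeric `(start_hpi, end_hpi)`. Defaults to
#'   `c(31, 43)` / `c(90, 113)` by study.
#' @param image_size Side length of the square frames in pixels.
#' @param rng_seed Integer seed controlling schedules, geometry and noise.
#' @param fragmentation_rate Fraction of the embryo volume rendered as
#'   extracellular debris, at most 0.15 (videos with more fragmentation are
#'   excluded from the modeled cohorts).
#' @param n_videos Number of videos drawn when simulating a dataset.
#' @param icm Render an inner-cell-mass blob in full blastocysts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(study = c("cells_stage", "blastocyst"),
                       category = c("transfer", "avoid"),
                       frames_per_hour = NULL,
                       window = NULL,
                       image_size = 250L,
                       rng_seed = 1L,
                       fragmentation_rate = 0.05,
                       n_videos = 1L,
                       icm = TRUE) {
  study <- match.arg(study)
  category <- match.arg(category)
  if (is.null(frames_per_hour)) {
    frames_per_hour <- if (study == "cells_stage") 4L else 8L
  }
  if (!frames_per_hour %in% c(3L, 4L, 8L)) {
    stop("frames_per_hour must be 3, 4 or 8", call. = FALSE)
  }
  if (is.null(window)) {
    window <- if (study == "cells_stage") c(31, 43) else c(90, 113)
  }
  if (length(window) != 2 || diff(window) < 1 / frames_per_hour) {
    stop("invalid config: window shorter than one inter-frame interval",
         call. = FALSE)
  }
  if (fragmentation_rate < 0 || fragmentation_rate > 0.15) {
    stop("fragmentation_rate must lie in [0, 0.15]", call. = FALSE)
  }
  structure(list(study = study, category = category,
                 frames_per_hour = as.integer(frames_per_hour),
                 window = as.numeric(window),
                 image_size = as.integer(image_size),
                 rng_seed = as.integer(rng_seed),
                 fragmentation_rate = fragmentation_rate,
                 n_videos = as.integer(n_videos), icm = icm),
            class = "sim_config")
}

# truncated-normal draw, clamped to keep event times ordered
rtnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  min(max(rnorm(1, mean, sd), lower), upper)
}

#' Draw a morphokinetic stage schedule
#'
#' Samples the developmental event timeline of one embryo. Cleavage-stage
#' schedules always enter the window in the 2-cell stage; blastocyst-study
#' "transfer" embryos enter at the start of compaction while "avoid" embryos
#' enter in the 9+ cell stage. "Transfer" division times are drawn from tight
#' distributions centered on typical morphokinetic timings (t3 around 36 hpi,
#' morula around 97 hpi, ...); "avoid" schedules draw delayed intervals and
#' arrest (no further events) with probability 0.3 (cleavage) / 0.35
#' (blastocyst).
#'
#' @param config A [sim_config()].
#' @return A `stage_schedule` data frame with columns `time_hpi`,
#'   `cell_count`, `stage_label`; times strictly increasing, counts
#'   non-decreasing.
#' @export
sample_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$rng_seed, {
    start <- config$window[1]
    ev <- if (config$study == "cells_stage") {
      evs <- data.frame(time_hpi = start, stage_label = "2cell")
      if (config$category == "transfer") {
        t3 <- rtnorm1(36, 0.75, start + 0.5)
        t4 <- t3 + abs(rnorm(1, 0.9, 0.3)) + 0.15
        t5 <- t4 + abs(rnorm(1, 4.5, 1.0)) + 0.25
        evs <- rbind(evs,
                     data.frame(time_hpi = c(t3, t4, t5),
                                stage_label = c("3cell", "4cell", "5to8cell")))
      } else if (runif(1) > 0.3) {  # avoid, not arrested
        t3 <- rtnorm1(38.5, 2.0, start + 0.5)
        t4 <- t3 + abs(rnorm(1, 2.5, 1.2)) + 0.15
        evs <- rbind(evs,
                     data.frame(time_hpi = c(t3, t4),
                                stage_label = c("3cell", "4cell")))
      }
      evs
    } else {
      if (config$category == "transfer") {
        tm <- rtnorm1(97, 1.5, start + 1)
        tb <- tm + abs(rnorm(1, 6.5, 1.5)) + 0.5
        tf <- tb + abs(rnorm(1, 6, 1.5)) + 0.5
        data.frame(time_hpi = c(start, tm, tb, tf),
                   stage_label = c("compaction", "morula",
                                   "blastocyst_start", "blastocyst_full"))
      } else {
        evs <- data.frame(time_hpi = start, stage_label = "9plus")
        if (runif(1) > 0.35) {  # not arrested
          tc <- rtnorm1(99, 2.5, start + 1)
          tm <- tc + abs(rnorm(1, 5, 2)) + 0.5
          tb <- tm + abs(rnorm(1, 6, 2)) + 0.5
          evs <- rbind(evs,
                       data.frame(time_hpi = c(tc, tm, tb),
                                  stage_label = c("compaction", "morula",
                                                  "blastocyst_start")))
        }
        evs
      }
    }
    ev$cell_count <- as.integer(STAGE_CELLS[ev$stage_label])
    ev <- ev[, c("time_hpi", "cell_count", "stage_label")]
    stopifnot(all(diff(ev$time_hpi) > 0), all(diff(ev$cell_count) >= 0))
    structure(ev, class = c("stage_schedule", "data.frame"))
  })
}

# video-level geometry drawn once per seed: embryo placement, orientation,
# rotation rate, background texture phases, fragment trajectories
video_geometry <- function(config) {
  with_local_seed(config$rng_seed * 7L + 13L, {
    nfrag <- round(config$fragmentation_rate * 30)
    list(
      cx = 0.5 + runif(1, -0.02, 0.02),
      cy = 0.5 + runif(1, -0.02, 0.02),
      theta0 = runif(1, 0, 2 * pi),
      omega = rnorm(1, 6, 2) * pi / 180,   # radians per hour
      bg_phase = runif(4, 0, 2 * pi),
      bg_freq = matrix(runif(8, 2, 7), 4, 2),
      frag_r = runif(nfrag, 0.25, 0.85),
      frag_a = runif(nfrag, 0, 2 * pi),
      frag_size = runif(nfrag, 0.05, 0.10),
      frag_f = runif(nfrag, 0.05, 0.2),
      frag_phi = runif(nfrag, 0, 2 * pi),
      icm_angle = runif(1, 0, 2 * pi),
      bump_phase = runif(1, 0, 2 * pi)
    )
  })
}

# smoothstep easing used for post-division settling and cavity growth
ease <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# positions of k blastomere centers (unit = fraction of the cell-region
# radius) and their radii, before global rotation
cell_layout <- function(k) {
  # spacings for k <= 4 leave a >= 0.05 R_cells gap between membranes even at
  # the maximum post-division settling inflation (1.06x), so thresholded
  # components always separate cleanly
  if (k <= 1) return(list(d = 0, a = 0, r = 0.90))
  if (k == 2) return(list(d = c(0.48, 0.48), a = c(0, pi), r = rep(0.42, 2)))
  if (k == 3) return(list(d = rep(0.52, 3), a = 2 * pi * (0:2) / 3, r = rep(0.40, 3)))
  if (k == 4) return(list(d = rep(0.56, 4), a = 2 * pi * (0:3) / 4 + pi / 4, r = rep(0.34, 4)))
  if (k <= 8) {
    inner <- list(d = c(0, 0.62), a = c(0, 0), r = c(0.34, 0.30))
    outer_n <- k - 2
    list(d = c(0.30, rep(0.64, outer_n), 0)[1:k],
         a = c(0, 2 * pi * (0:(outer_n - 1)) / outer_n, 0)[1:k],
         r = c(0.34, rep(0.30, outer_n), 0.30)[1:k])
  } else {
    list(d = c(0, rep(0.62, 8), rep(0.33, k - 9))[1:k],
         a = c(0, 2 * pi * (0:7) / 8, 2 * pi * (0:max(0, k - 10)) / max(1, k - 9) + 0.4)[1:k],
         r = rep(0.27, k))
  }
}

#' Render one synthetic frame
#'
#' Deterministically renders the embryo at time `t_hpi` given its stage
#' schedule: k shaded blastomere discs with bright membranes packed inside the
#' zona pellucida ring, a textured microwell background, optional
#' fragmentation debris, and for blastocyst stages an expanding blastocoel
#' cavity with trophectoderm band. Continuous dynamics (slow rotation,
#' post-division settling, cavity growth, fragment drift) plus per-frame
#' camera noise and illumination flicker emulate real incubator footage.
#' Intensities are clamped to the 8-bit range.
#'
#' @param schedule A [sample_schedule()] result.
#' @param t_hpi Acquisition time in hours post insemination, inside the window.
#' @param config The [sim_config()] that produced the schedule.
#' @param with_mask Also return the true embryo foreground mask.
#' @return Integer matrix (`image_size` square, values 0--255); if
#'   `with_mask`, a list `(frame, mask)` with a binary mask matrix.
#' @export
render_frame <- function(schedule, t_hpi, config, with_mask = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$image_size
  geo <- video_geometry(config)
  start <- config$window[1]

  # active event at t
  idx <- max(which(schedule$time_hpi <= t_hpi + 1e-9), 1)
  stage <- schedule$stage_label[idx]
  k <- schedule$cell_count[idx]
  t_event <- schedule$time_hpi[idx]

  px <- (col(matrix(0, s, s)) - 0.5) / s   # x in (0,1)
  py <- (row(matrix(0, s, s)) - 0.5) / s
  dx <- px - geo$cx
  dy <- py - geo$cy
  rr <- sqrt(dx^2 + dy^2)

  R_zona <- 0.36
  zona_w <- 0.045
  R_cells <- R_zona - zona_w - 0.02

  # blastocyst-phase embryo expansion
  expand <- 1
  cav_prog <- 0
  if (stage %in% c("blastocyst_start", "blastocyst_full")) {
    t_bs <- schedule$time_hpi[match("blastocyst_start", schedule$stage_label)]
    t_bf <- if ("blastocyst_full" %in% schedule$stage_label) {
      schedule$time_hpi[match("blastocyst_full", schedule$stage_label)]
    } else {
      t_bs + 6
    }
    cav_prog <- ease((t_hpi - t_bs) / max(t_bf - t_bs, 1e-6))
    expand <- 1 + 0.10 * cav_prog
  }
  R_zona <- R_zona * expand
  R_cells <- R_cells * expand

  img <- matrix(35, s, s)
  # microwell floor with smooth static texture
  well <- rr < 0.47
  tex <- matrix(0, s, s)
  for (m in 1:4) {
    tex <- tex + sin(2 * pi * (geo$bg_freq[m, 1] * px + geo$bg_freq[m, 2] * py) +
                       geo$bg_phase[m])
  }
  img[well] <- 45 + 1.5 * tex[well]
  # well ring
  ring <- abs(rr - 0.47) < 0.008
  img[ring] <- 90
  # perivitelline space and zona pellucida
  inside <- rr < R_zona
  img[inside] <- 95
  zona <- rr >= (R_zona - zona_w) & rr < R_zona
  img[zona] <- 120

  theta <- geo$theta0 + geo$omega * (t_hpi - start)
  put_disc <- function(img, cx, cy, radius, fill, membrane = NA,
                       shade = TRUE, bump = 0) {
    ddx <- px - cx
    ddy <- py - cy
    d <- sqrt(ddx^2 + ddy^2)
    rad <- radius
    if (bump > 0) {
      ang <- atan2(ddy, ddx)
      rad <- radius * (1 + bump * sin(6 * ang + geo$bump_phase))
    }
    core <- d < rad
    if (shade) {
      img[core] <- fill - 20 * (d[core] / radius)^2 * (fill / 170)
    } else {
      img[core] <- fill
    }
    if (!is.na(membrane)) {
      memb <- d >= rad * 0.90 & d < rad
      img[memb] <- membrane
    }
    img
  }

  if (stage %in% c("2cell", "3cell", "4cell", "5to8cell", "9plus")) {
    # post-division settling: cells shrink from 1.06x over 30 min
    settle <- 1 + 0.06 * (1 - ease((t_hpi - t_event) / 0.5))
    lay <- cell_layout(k)
    for (i in seq_len(k)) {
      a <- lay$a[i] + theta
      cxi <- geo$cx + lay$d[i] * R_cells * cos(a)
      cyi <- geo$cy + lay$d[i] * R_cells * sin(a)
      img <- put_disc(img, cxi, cyi, lay$r[i] * R_cells * min(settle, 1.06),
                      fill = 170, membrane = 220)
    }
  } else if (stage %in% c("compaction", "morula")) {
    frac <- if (stage == "morula") 0.70 else 0.75
    bump <- if (stage == "morula") 0.06 else 0.03
    img <- put_disc(img, geo$cx, geo$cy, frac * R_cells, fill = 165,
                    membrane = 210, bump = bump)
  } else {
    # blastocyst: cell band fills the embryo, cavity grows as a dark disc
    img <- put_disc(img, geo$cx, geo$cy, 0.95 * R_cells, fill = 160,
                    membrane = NA)
    # trophectoderm band just inside the zona
    band <- rr >= (R_zona - zona_w - 0.035 * expand) & rr < (R_zona - zona_w)
    img[band] <- 200
    cav_r <- (0.25 + 0.50 * cav_prog) * R_cells
    cav_off <- 0.30 * R_cells
    ccx <- geo$cx + cav_off * cos(geo$icm_angle + pi)
    ccy <- geo$cy + cav_off * sin(geo$icm_angle + pi)
    img <- put_disc(img, ccx, ccy, cav_r, fill = 75, membrane = NA, shade = FALSE)
    if (config$icm && stage == "blastocyst_full") {
      icx <- geo$cx + 0.55 * R_cells * cos(geo$icm_angle)
      icy <- geo$cy + 0.55 * R_cells * sin(geo$icm_angle)
      img <- put_disc(img, icx, icy, 0.30 * R_cells, fill = 185, membrane = NA)
    }
  }

  # fragmentation debris drifting slowly in the perivitelline space
  nfrag <- length(geo$frag_r)
  if (nfrag > 0) {
    for (i in seq_len(nfrag)) {
      wob <- 0.03 * sin(2 * pi * geo$frag_f[i] * (t_hpi - start) + geo$frag_phi[i])
      fa <- geo$frag_a[i] + theta * 0.5
      fx <- geo$cx + (geo$frag_r[i] * R_cells + wob) * cos(fa)
      fy <- geo$cy + (geo$frag_r[i] * R_cells + wob) * sin(fa)
      img <- put_disc(img, fx, fy, geo$frag_size[i] * R_cells, fill = 118,
                      membrane = NA, shade = FALSE)
    }
  }

  # sensor noise and LED illumination flicker, seeded per frame
  noise_seed <- (config$rng_seed * 7919L +
                   as.integer(round((t_hpi %% 1000) * 3600))) %% 2147483647L
  img <- with_local_seed(noise_seed, {
    gain <- rnorm(1, 1, 0.008)
    img * gain + matrix(rnorm(s * s, 0, 4), s, s)
  })
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), s, s)

  if (with_mask) {
    list(frame = img, mask = matrix(as.integer(inside | zona), s, s))
  } else {
    img
  }
}

#' Simulate one annotated video
#'
#' Samples a stage schedule and renders frames on the half-open acquisition
#' grid `[start_hpi, end_hpi)` with spacing `1/frames_per_hour`, so a video
#' holds exactly `floor((end - start) * frames_per_hour)` frames. Per-frame
#' annotations (hpi, cell count, stage label) are derived from the schedule.
#'
#' @param config A [sim_config()].
#' @param with_masks Also keep the true embryo foreground mask of every frame
#'   (used to train the embryo cropper on exact labels).
#' @return An `annotated_video`: list with `frames` (list of 8-bit integer
#'   matrices), `annotations` (data frame `frame_index`, `hpi`, `cell_count`,
#'   `stage_label`), `schedule`, `config`, and optionally `masks`.
#' @export
simulate_video <- function(config, with_masks = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  schedule <- sample_schedule(config)
  n <- floor(diff(config$window) * config$frames_per_hour + 1e-9)
  hpi <- config$window[1] + (seq_len(n) - 1) / config$frames_per_hour
  frames <- vector("list", n)
  masks <- if (with_masks) vector("list", n) else NULL
  for (i in seq_len(n)) {
    r <- render_frame(schedule, hpi[i], config, with_mask = with_masks)
    if (with_masks) {
      frames[[i]] <- r$frame
      masks[[i]] <- r$mask
    } else {
      frames[[i]] <- r
    }
  }
  idx <- vapply(hpi, function(t) max(which(schedule$time_hpi <= t + 1e-9), 1L),
                integer(1))
  ann <- data.frame(frame_index = seq_len(n), hpi = hpi,
                    cell_count = schedule$cell_count[idx],
                    stage_label = schedule$stage_label[idx])
  out <- list(frames = frames, annotations = ann, schedule = schedule,
              config = config)
  if (with_masks) out$masks <- masks
  structure(out, class = "annotated_video")
}

#' Simulate a dataset of videos
#'
#' Draws `config$n_videos` videos with distinct per-video seeds derived
#' deterministically from the config seed.
#'
#' @param config A [sim_config()] with `n_videos` set.
#' @param with_masks Passed to [simulate_video()].
#' @return List of `annotated_video` objects, named `video_0001`, ...
#' @export
simulate_videos <- function(config, with_masks = FALSE) {
  out <- lapply(seq_len(config$n_videos), function(i) {
    ci <- config
    ci$rng_seed <- as.integer((config$rng_seed + i * 9973) %% 2147483647)
    simulate_video(ci, with_masks = with_masks)
  })
  names(out) <- sprintf("video_%04d", seq_along(out))
  out
}

#' Write a simulated dataset to disk
#'
#' Layout: one directory per video holding zero-padded `frame_%04d.png`
#' images, an `annotations.csv` (`frame_index,hpi,cell_count,stage_label`), a
#' `metadata.yaml` with the generating config, and (when masks are present) a
#' `masks/` subdirectory; plus a root-level `manifest.csv`.
#'
#' @param videos List of `annotated_video` objects (see [simulate_videos()]).
#' @param root Output directory (created if missing).
#' @return The manifest data frame, invisibly readable back via
#'   [read_manifest()].
#' @export
write_dataset <- function(videos, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("cannot create dataset root: ", root, call. = FALSE)
  ids <- names(videos)
  if (is.null(ids)) ids <- sprintf("video_%04d", seq_along(videos))
  rows <- lapply(seq_along(videos), function(i) {
    v <- videos[[i]]
    vdir <- file.path(root, ids[i])
    dir.create(vdir, showWarnings = FALSE)
    for (j in seq_along(v$frames)) {
      png::writePNG(v$frames[[j]] / 255,
                    file.path(vdir, sprintf("frame_%04d.png", j)))
    }
    if (!is.null(v$masks)) {
      mdir <- file.path(vdir, "masks")
      dir.create(mdir, showWarnings = FALSE)
      for (j in seq_along(v$masks)) {
        png::writePNG(v$masks[[j]] * 1.0,
                      file.path(mdir, sprintf("frame_%04d.png", j)))
      }
    }
    write.csv(v$annotations, file.path(vdir, "annotations.csv"),
              row.names = FALSE)
    yaml::write_yaml(unclass(v$config), file.path(vdir, "metadata.yaml"))
    data.frame(video_id = ids[i], study = v$config$study,
               category = v$config$category, n_frames = length(v$frames),
               frames_per_hour = v$config$frames_per_hour,
               rng_seed = v$config$rng_seed)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset manifest
#' @param root Dataset directory written by [write_dataset()].
#' @return Manifest data frame.
#' @export
read_manifest <- function(root) {
  path <- file.path(root, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv under ", root, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}
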