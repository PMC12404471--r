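# Synthetic embryo video simulator: schedules, rendering, dataset layout.

count_components <- function(frame, threshold = 128, min_area_frac = 0.004) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(frame > threshold)))
  tab <- tabulate(lab[lab > 0])
  sum(tab >= min_area_frac * length(frame))
}

test_that("configs are validated", {
  expect_error(sim_config(frames_per_hour = 5), "frames_per_hour")
  expect_error(sim_config(fragmentation_rate = 0.2), "fragmentation_rate")
  expect_error(sim_config(window = c(31, 31.1), frames_per_hour = 4),
               "invalid config")
})

test_that("schedules respect study entry stages and ordering", {
  for (seed in 1:8) {
    s <- sample_schedule(sim_config("cells_stage", "transfer", rng_seed = seed))
    expect_identical(s$stage_label[1], "2cell")
    expect_lte(s$time_hpi[1], 31)
    expect_true(all(diff(s$time_hpi) > 0))
    expect_true(all(diff(s$cell_count) >= 0))

    bt <- sample_schedule(sim_config("blastocyst", "transfer", rng_seed = seed))
    expect_identical(bt$stage_label[1], "compaction")
    ba <- sample_schedule(sim_config("blastocyst", "avoid", rng_seed = seed))
    expect_identical(ba$stage_label[1], "9plus")
  }
})

test_that("identical seeds give identical schedules and frames", {
  cfg <- sim_config("cells_stage", "avoid", rng_seed = 7, image_size = 96)
  expect_identical(sample_schedule(cfg), sample_schedule(cfg))
  v1 <- simulate_video(cfg)
  v2 <- simulate_video(cfg)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$annotations, v2$annotations)
})

test_that("avoid schedules are delayed or arrested relative to transfer", {
  t3 <- function(category, seed) {
    s <- sample_schedule(sim_config("cells_stage", category, rng_seed = seed))
    if ("3cell" %in% s$stage_label) s$time_hpi[match("3cell", s$stage_label)]
    else Inf  # arrested
  }
  tt <- vapply(1:12, t3, numeric(1), category = "transfer")
  ta <- vapply(1:12, t3, numeric(1), category = "avoid")
  expect_true(all(is.finite(tt)))
  expect_gt(mean(pmin(ta, 43)), mean(tt))
})

test_that("frame counts follow the half-open acquisition grid", {
  v <- simulate_video(sim_config("cells_stage", "transfer", rng_seed = 1,
                                 frames_per_hour = 4, image_size = 64))
  expect_length(v$frames, (43 - 31) * 4)
  vb <- simulate_video(sim_config("blastocyst", "transfer", rng_seed = 1,
                                  frames_per_hour = 8, image_size = 64))
  expect_length(vb$frames, (113 - 90) * 8)
  # annotations: one row per frame, uniform strictly increasing hpi
  expect_identical(nrow(v$annotations), length(v$frames))
  expect_equal(diff(v$annotations$hpi), rep(1 / 4, length(v$frames) - 1))
  expect_true(all(diff(v$annotations$cell_count) >= 0))
})

test_that("rendered component count matches annotated cell count (<= 4 cells)", {
  for (seed in c(11, 12, 13)) {
    v <- fix_video()
    if (seed != 11) {
      v <- simulate_video(sim_config("cells_stage", "transfer",
                                     rng_seed = seed, image_size = 128))
    }
    ann <- v$annotations
    sel <- which(ann$cell_count <= 4)
    counts <- vapply(v$frames[sel], count_components, numeric(1))
    expect_equal(unname(counts), ann$cell_count[sel])
  }
})

test_that("frames are 8-bit and masks cover the embryo disc", {
  v <- fix_video()
  expect_in_range(unlist(v$frames[c(1, 20)]), 0, 255)
  m <- v$masks[[1]]
  expect_setequal(unique(as.vector(m)), c(0L, 1L))
  # mask area close to the zona disc area (pi * 0.36^2 of the frame)
  expect_equal(mean(m), pi * 0.36^2, tolerance = 0.06)
})

test_that("background-only render has no foreground above threshold in the ring", {
  cfg <- sim_config("cells_stage", "transfer", rng_seed = 5, image_size = 128)
  sch <- sample_schedule(cfg)
  sch$cell_count[] <- 0L  # force an empty embryo
  f <- render_frame(sch, 32, cfg)
  expect_identical(count_components(f), 0L)
})

test_that("datasets round-trip losslessly through the on-disk layout", {
  root <- withr::local_tempdir()
  cfg <- sim_config("cells_stage", "transfer", rng_seed = 3, n_videos = 2,
                    image_size = 64)
  vids <- simulate_videos(cfg, with_masks = TRUE)
  manifest <- write_dataset(vids, root)
  expect_identical(nrow(manifest), 2L)
  expect_identical(sort(list.dirs(root, recursive = FALSE, full.names = FALSE)),
                   c("video_0001", "video_0002"))
  expect_identical(manifest$study, rep("cells_stage", 2))
  expect_identical(manifest$category, rep("transfer", 2))

  rt <- read_video(file.path(root, "video_0001"))
  expect_identical(rt$frames, vids$video_0001$frames)
  expect_equal(rt$annotations$hpi, vids$video_0001$annotations$hpi)
  expect_identical(rt$masks, vids$video_0001$masks)
  expect_identical(read_manifest(root)$video_id, manifest$video_id)
})

test_that("read_video validates its inputs", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "v1"))
  expect_error(read_video(file.path(root, "v1")), "annotations.csv")
})
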