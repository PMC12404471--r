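# Shared fixtures, built once per test run and memoized. Everything is
# generated in code at fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small cleavage-stage video at reduced resolution (fast to simulate)
fix_video <- function() {
  memo("video", function() {
    simulate_video(sim_config("cells_stage", "transfer", rng_seed = 101,
                              image_size = 128), with_masks = TRUE)
  })
}

# desk-scale study config used by bookkeeping tests
fix_scfg_small <- function() study_config("cells_stage", H = 16L, W = 16L)

# a minimal untrained predictor for index-bookkeeping tests (16 x 16 frames,
# 2-filter layers): predictions are meaningless but shapes and provenance
# are exact
fix_tiny_predictor <- function() {
  memo("tiny_predictor", function() {
    mcfg <- model_config(fix_scfg_small(), "tiny",
                         filters = c(2L, 2L, 2L, 2L),
                         kernels = c(3L, 3L, 3L, 1L))
    build_frame_predictor(mcfg, seed = 3)
  })
}

# a 15-frame preprocessed synthetic video at 16 x 16 (the worked example
# size of the forecasting strategies)
fix_pvideo15 <- function() {
  memo("pvideo15", function() {
    v <- fix_video()
    v$frames <- v$frames[1:15]
    v$annotations <- v$annotations[1:15, ]
    preprocess_video(v, fix_scfg_small())
  })
}

expect_in_range <- function(x, lo, hi) {
  expect_true(all(x >= lo & x <= hi),
              label = sprintf("values in [%g, %g]", lo, hi))
}
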