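# Preprocessing: channel stacking, normalization, sliding windows, splits.

test_that("resize_and_normalize produces 3 identical channels in [0,1]", {
  out <- resize_and_normalize(matrix(255L, 250, 250), 128, 128)
  expect_identical(dim(out), c(128L, 128L, 3L))
  expect_equal(max(abs(out - 1)), 0)
  out0 <- resize_and_normalize(matrix(0L, 40, 40), 32, 32)
  expect_equal(max(abs(out0)), 0)
  # arbitrary content: channels identical, range preserved
  set.seed(1)
  f <- matrix(sample(0:255, 250 * 250, TRUE), 250, 250)
  r <- resize_and_normalize(f, 128, 128)
  expect_identical(r[, , 1], r[, , 2])
  expect_identical(r[, , 1], r[, , 3])
  expect_in_range(r, 0, 1)
  expect_error(resize_and_normalize(array(0, c(4, 4, 2)), 4, 4), "2-D")
})

test_that("time normalization is min-max over the window and clipped", {
  expect_equal(normalize_time(31, c(31, 43)), 0)
  expect_equal(normalize_time(43, c(31, 43)), 1)
  expect_equal(normalize_time(37, c(31, 43)), 0.5)
  expect_equal(normalize_time(30, c(31, 43)), 0)
  expect_equal(normalize_time(44, c(31, 43)), 1)
  expect_error(normalize_time(1, c(5, 5)), "degenerate")
})

test_that("channel stacking matches the study depth with constant aux planes", {
  img3 <- array(runif(16 * 16 * 3), c(16, 16, 3))
  cs <- stack_channels(img3, 37, 4, study_config("cells_stage", H = 16, W = 16))
  expect_identical(dim(cs), c(16L, 16L, 5L))
  expect_equal(sd(cs[, , 4]), 0)
  expect_equal(sd(cs[, , 5]), 0)
  expect_equal(cs[1, 1, 4], 0.5)
  expect_equal(cs[1, 1, 5], 4 / 9)

  bl <- stack_channels(img3, 101.5, NULL, study_config("blastocyst", H = 16, W = 16))
  expect_identical(dim(bl), c(16L, 16L, 4L))
  expect_equal(bl[1, 1, 4], (101.5 - 90) / 23)
  expect_error(
    stack_channels(img3, 37, NULL, study_config("cells_stage", H = 16, W = 16)),
    "cell_count")
})

test_that("preprocessed frames stay in [0,1] with no NaNs", {
  pv <- fix_pvideo15()
  expect_false(anyNA(pv$frames))
  expect_in_range(pv$frames, 0, 1)
})

test_that("sliding windows reproduce the worked 12-frame example", {
  arr <- array(runif(8 * 8 * 4 * 12), c(8, 8, 4, 12))
  pairs <- build_subsequences(arr, F = 7)
  expect_length(pairs, 5)
  expect_identical(vapply(pairs, `[[`, numeric(1), "target_index"),
                   as.numeric(8:12))
  expect_identical(pairs[[1]]$start_index, 1L)
  expect_equal(pairs[[1]]$input, arr[, , , 1:7])
  expect_equal(pairs[[5]]$target, arr[, , , 12])
})

test_that("window counts equal brute-force enumeration for N = 8..30", {
  # oracle: enumerate every consecutive (7-frame window, next frame) pair
  enumerate_pairs <- function(N, F = 7) {
    out <- list()
    for (s in seq_len(N)) {
      if (s + F <= N) out[[length(out) + 1L]] <- c(start = s, target = s + F)
    }
    out
  }
  for (N in 8:30) {
    arr <- array(0, c(4, 4, 4, N))
    pairs <- build_subsequences(arr, F = 7)
    oracle <- enumerate_pairs(N)
    expect_length(pairs, length(oracle))
    expect_equal(vapply(pairs, `[[`, integer(1), "start_index"),
                 vapply(oracle, function(o) unname(o["start"]), numeric(1)))
    expect_identical(vapply(pairs, `[[`, numeric(1), "target_index"),
                     vapply(oracle, function(o) unname(as.numeric(o["target"])),
                            numeric(1)))
  }
  # too-short videos yield an empty list
  expect_length(build_subsequences(array(0, c(4, 4, 4, 7)), F = 7), 0)
  expect_length(build_subsequences(array(0, c(4, 4, 4, 8)), F = 7), 1)
})

test_that("pairs preserve acquisition order", {
  pv <- fix_pvideo15()
  pairs <- build_subsequences(pv)
  for (p in pairs[c(1, 4, 8)]) {
    hpis <- pv$hpi[p$start_index:(p$start_index + 6)]
    expect_true(all(diff(hpis) > 0))
    expect_gt(p$target_hpi, max(hpis))
  }
})

test_that("train/val split is at video level, seeded, 80:20", {
  ids <- sprintf("v%02d", 1:10)
  sp <- split_train_val(ids, 0.8, seed = 4)
  expect_length(sp$train, 8)
  expect_length(sp$val, 2)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), ids)
  expect_identical(sp, split_train_val(ids, 0.8, seed = 4))
  expect_false(identical(sp, split_train_val(ids, 0.8, seed = 5)))
  expect_error(split_train_val(ids, 1.2), "ratio")
  expect_error(split_train_val("v1"), "at least 2")
})
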