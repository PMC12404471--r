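# Recursive forecasting strategies: exact index bookkeeping against
# hand-enumerated tables of the 15-frame worked example.

test_that("till_end on 15 frames predicts labels 8..15 with predicted feedback", {
  pv <- fix_pvideo15()
  model <- fix_tiny_predictor()
  fc <- forecast_till_end(model, pv$frames, pv$hpi, n_total = 15)
  expect_length(fc$entries, 8)

  # hand enumeration: entry for label L uses window L-7..L-1; frames 1..7
  # are real, everything later predicted; horizon = L - 7
  for (e in fc$entries) {
    L <- e$frame_label
    expect_equal(e$inputs_used$frame_label, (L - 7):(L - 1))
    expect_identical(e$inputs_used$source,
                     ifelse((L - 7):(L - 1) <= 7, "real", "predicted"))
    expect_equal(e$horizon, L - 7)
  }
  labs <- vapply(fc$entries, `[[`, numeric(1), "frame_label")
  expect_equal(labs, as.numeric(8:15))
  # entry for frame 9 lists x2..x7 real plus predicted 8
  e9 <- fc$entries[[2]]
  expect_equal(e9$inputs_used$frame_label, 2:8)
  expect_identical(e9$inputs_used$source, c(rep("real", 6), "predicted"))
})

test_that("till_end edge cases and feedback channel handling", {
  pv <- fix_pvideo15()
  model <- fix_tiny_predictor()
  fc1 <- forecast_till_end(model, pv$frames, pv$hpi, n_total = 8)
  expect_length(fc1$entries, 1)
  expect_equal(fc1$entries[[1]]$horizon, 1)
  expect_error(forecast_till_end(model, pv$frames[, , , 1:3, drop = FALSE],
                                 pv$hpi), "at least F")
  # schedule feedback: the recursed input's time plane is overwritten with
  # the true normalized acquisition time and the cell-count plane collapses
  # to its spatial mean (raw mode leaves the prediction untouched)
  fc <- forecast_till_end(model, pv$frames, pv$hpi, n_total = 12)
  e <- fc$entries[[3]]
  expect_in_range(e$full, 0, 1)
  fb <- embryocast:::feedback_frame(e$full, pv$hpi[e$frame_label],
                                    model$mcfg, "schedule")
  expect_equal(sd(fb[, , 4]), 0)
  expect_equal(fb[1, 1, 4], normalize_time(pv$hpi[e$frame_label],
                                           model$mcfg$time_window))
  expect_equal(sd(fb[, , 5]), 0)
  expect_equal(fb[1, 1, 5], mean(e$full[, , 5]))
  expect_identical(embryocast:::feedback_frame(e$full, 40, model$mcfg, "raw"),
                   e$full)
})

test_that("next7 reproduces the 15-frame rolling update scheme", {
  pv <- fix_pvideo15()
  model <- fix_tiny_predictor()
  fc <- forecast_next7(model, pv$frames, pv$hpi)
  # two updates of exactly 7 entries each
  upd <- vapply(fc$entries, `[[`, integer(1), "update")
  expect_equal(as.integer(table(upd)), c(7L, 7L))
  labs <- vapply(fc$entries, `[[`, numeric(1), "frame_label")
  expect_equal(labs[upd == 1], as.numeric(8:14))
  expect_equal(labs[upd == 2], as.numeric(9:15))
  hor <- vapply(fc$entries, `[[`, numeric(1), "horizon")
  expect_equal(hor[upd == 1], as.numeric(1:7))
  expect_equal(hor[upd == 2], as.numeric(1:7))

  # update 1, label 8: real window x1..x7
  e8 <- fc$entries[[1]]
  expect_equal(e8$inputs_used$frame_label, 1:7)
  expect_identical(unique(e8$inputs_used$source), "real")
  # update 1, label 14: inputs x7 real + predicted 8..13
  e14 <- fc$entries[[7]]
  expect_equal(e14$inputs_used$frame_label, 7:13)
  expect_identical(e14$inputs_used$source, c("real", rep("predicted", 6)))
  # update 2 advances on real frames only: label 9 now uses x2..x8 all real
  e9 <- fc$entries[[8]]
  expect_equal(e9$inputs_used$frame_label, 2:8)
  expect_identical(unique(e9$inputs_used$source), "real")
})

test_that("next7 supersession: interior labels predicted 7 times at horizons 7..1", {
  v <- fix_video()
  v$frames <- v$frames[1:21]
  v$annotations <- v$annotations[1:21, ]
  pv <- preprocess_video(v, fix_scfg_small())
  model <- fix_tiny_predictor()
  fc <- forecast_next7(model, pv$frames, pv$hpi)
  prov <- do.call(rbind, lapply(fc$entries, function(e) {
    data.frame(label = e$frame_label, horizon = e$horizon, update = e$update)
  }))
  l14 <- prov[prov$label == 14, ]
  expect_identical(nrow(l14), 7L)
  expect_equal(l14$horizon[order(l14$update)], 7:1)
  # real frames are never replaced by predictions once available: horizon-1
  # entries always use all-real windows
  h1 <- Filter(function(e) e$horizon == 1, fc$entries)
  for (e in h1) expect_identical(unique(e$inputs_used$source), "real")
})

test_that("assemble_forecast_video policies select the right entries", {
  pv <- fix_pvideo15()
  model <- fix_tiny_predictor()
  fc <- forecast_next7(model, pv$frames, pv$hpi)
  latest <- assemble_forecast_video(fc, "latest")
  expect_identical(latest$provenance$frame_label, as.numeric(8:15))
  # label 8 was only ever predicted in update 1; 9..15 come from update 2
  expect_identical(latest$provenance$update, c(1L, rep(2L, 7)))
  byh <- assemble_forecast_video(fc, "by_horizon", h = 1)
  expect_true(all(byh$provenance$frame_label %in% latest$provenance$frame_label))
  expect_true(all(byh$provenance$horizon == 1))
  expect_error(assemble_forecast_video(fc, "by_horizon", h = 9), "horizon")

  te <- forecast_till_end(model, pv$frames, pv$hpi, n_total = 15)
  a1 <- assemble_forecast_video(te, "latest")
  a2 <- assemble_forecast_video(te, "by_horizon", h = 3)
  expect_identical(a1$provenance$frame_label[3],
                   a2$provenance$frame_label[1])
  expect_equal(a1$frames[[3]], a2$frames[[1]])
})

test_that("till_end count law holds for all n_total >= F+1 (enumeration oracle)", {
  pv <- fix_pvideo15()
  model <- fix_tiny_predictor()
  for (n in 8:15) {
    fc <- forecast_till_end(model, pv$frames, pv$hpi, n_total = n)
    expect_length(fc$entries, n - 7)
  }
})

test_that("inference is deterministic and within (0,1)", {
  pv <- fix_pvideo15()
  model <- fix_tiny_predictor()
  w <- pv$frames[, , , 1:7, drop = FALSE]
  p1 <- predict_next_frame(model, w)
  p2 <- predict_next_frame(model, w)
  expect_identical(p1, p2)
  expect_true(all(p1$image > 0 & p1$image < 1))
  expect_true(all(p1$full > 0 & p1$full < 1))
  expect_error(predict_next_frame(model, pv$frames[, , , 1:6, drop = FALSE]),
               "window")
})
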