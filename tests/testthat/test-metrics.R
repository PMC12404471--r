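# Quality metrics: PSNR / SSIM closed forms and reference agreement,
# Fréchet distance, FVD behavior.

test_that("psnr matches closed forms and caps at zero error", {
  a <- matrix(0.3, 32, 32)
  expect_equal(psnr(a, a), 100)
  expect_equal(psnr(matrix(0, 32, 32), matrix(1, 32, 32)), 0)
  expect_equal(psnr(matrix(0.2, 32, 32), matrix(0.7, 32, 32)),
               10 * log10(1 / 0.25), tolerance = 1e-10)
  expect_error(psnr(matrix(0, 3, 3), matrix(0, 4, 4)), "shape")
})

test_that("ssim closed forms: identity, symmetry, constant images", {
  set.seed(9)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  # two constant images 0 and 1: S = C1 / (mu1^2 + mu2^2 + C1)
  C1 <- 0.01^2
  expect_equal(ssim(matrix(0, 32, 32), matrix(1, 32, 32)), C1 / (1 + C1),
               tolerance = 1e-12)
  expect_error(ssim(matrix(0, 5, 5), matrix(0, 5, 5)), "window")
})

test_that("ssim and psnr agree with the scikit-image reference values", {
  # frozen outputs of skimage.metrics.structural_similarity (data_range=1,
  # gaussian_weights=TRUE, sigma=1.5, use_sample_covariance=FALSE) and
  # peak_signal_noise_ratio on the seed-42 pairs below
  ssim_expected <- c(0.009274850080, -0.008371101628, -0.023201823402,
                     0.006686664663, 0.015676749949, 0.033627683689,
                     0.006292496437, -0.009001108399, 0.023522807552,
                     -0.010497649922)
  psnr_expected <- c(7.679241978435, 7.676944271677, 7.743547599964,
                     7.743062504747, 7.794789730789, 7.786534052242,
                     7.741245865205, 7.714628422541, 7.822172944561,
                     7.696357481321)
  set.seed(42)
  for (i in 1:10) {
    a <- matrix(runif(64 * 64), 64, 64)
    b <- matrix(runif(64 * 64), 64, 64)
    expect_equal(ssim(a, b), ssim_expected[i], tolerance = 1e-6)
    expect_equal(psnr(a, b), psnr_expected[i], tolerance = 1e-6)
  }
})

test_that("frechet distance matches 1-D and diagonal closed forms", {
  expect_equal(frechet_distance(0, matrix(1), 3, matrix(1)), 9,
               tolerance = 1e-8)
  expect_equal(frechet_distance(c(1, 2), diag(2), c(1, 2), diag(2)), 0,
               tolerance = 1e-10)
  # diagonal covariances: sum_i (mu1i-mu2i)^2 + (sqrt(s1i)-sqrt(s2i))^2
  set.seed(3)
  for (rep in 1:5) {
    d <- 4
    mu1 <- rnorm(d); mu2 <- rnorm(d)
    s1 <- runif(d, 0.1, 2); s2 <- runif(d, 0.1, 2)
    closed <- sum((mu1 - mu2)^2) + sum((sqrt(s1) - sqrt(s2))^2)
    expect_equal(frechet_distance(mu1, diag(s1), mu2, diag(s2)), closed,
                 tolerance = 1e-8)
  }
  expect_error(frechet_distance(0, matrix(1), c(0, 0), diag(2)), "dimension")
})

test_that("frechet distance is symmetric and zero iff moments coincide", {
  set.seed(5)
  for (rep in 1:4) {
    d <- 5
    A <- matrix(rnorm(d * d), d); S1 <- crossprod(A) / d
    B <- matrix(rnorm(d * d), d); S2 <- crossprod(B) / d
    mu1 <- rnorm(d); mu2 <- rnorm(d)
    f12 <- frechet_distance(mu1, S1, mu2, S2)
    f21 <- frechet_distance(mu2, S2, mu1, S1)
    expect_equal(f12, f21, tolerance = 1e-8)
    expect_gt(f12, 0)
    expect_lt(frechet_distance(mu1, S1, mu1, S1), 1e-6)
  }
})

test_that("the sequence embedder is deterministic and temporally sensitive", {
  set.seed(11)
  frames <- array(runif(16 * 16 * 3 * 8), c(16, 16, 3, 8))
  # moving blob so permutations genuinely change the dynamics
  for (t in 1:8) frames[t:(t + 3), 4:8, , t] <- 1
  spec <- embedder_spec(dim = 32, seed = 7)
  e1 <- embed_sequence(frames, spec)
  e2 <- embed_sequence(frames, spec)
  expect_identical(e1, e2)
  expect_length(e1, 32)
  perm <- frames[, , , c(5, 2, 7, 1, 8, 3, 6, 4)]
  expect_gt(max(abs(embed_sequence(perm, spec) - e1)), 1e-8)
  expect_error(embed_sequence(frames[, , , 1, drop = FALSE], spec),
               "at least 2")
})

test_that("fvd is zero for identical sets and grows with noise", {
  set.seed(13)
  seqs <- lapply(1:4, function(i) {
    arr <- array(runif(16 * 16 * 3 * 12) * 0.5, c(16, 16, 3, 12))
    for (t in 1:12) arr[max(1, t - 1):min(16, t + 1), , , t] <- 0.9
    arr
  })
  spec <- embedder_spec(dim = 16, seed = 5)
  expect_lt(fvd_score(seqs, seqs, truncate_at = 10, spec = spec), 1e-6)
  noisy <- function(sig) lapply(seqs, function(s) {
    pmin(pmax(s + array(rnorm(length(s), 0, sig), dim(s)), 0), 1)
  })
  f_small <- fvd_score(seqs, noisy(0.05), truncate_at = 10, spec = spec)
  f_big <- fvd_score(seqs, noisy(0.3), truncate_at = 10, spec = spec)
  expect_gt(f_small, 0)
  expect_gt(f_big, f_small)
  # short sequences are skipped; too few sequences fail
  expect_warning(
    expect_error(
      fvd_score(seqs[1:2], lapply(seqs[1:2], function(s) s[, , , 1:5]),
                truncate_at = 10, spec = spec),
      "at least 2"),
    "skipping")
})

test_that("fvd presets match both studies", {
  expect_identical(fvd_presets("cells_stage"), c(10L, 14L, 28L))
  expect_identical(fvd_presets("blastocyst"), c(60L, 120L, 180L))
})

test_that("report means equal the arithmetic mean of per-frame values", {
  pv <- fix_pvideo15()
  model <- fix_tiny_predictor()
  fc <- forecast_till_end(model, pv$frames, pv$hpi, n_total = 15)
  rep <- evaluate_forecast(pv$frames, fc, truncations = c(4L))
  expect_equal(rep$uncropped$mean_psnr, mean(rep$uncropped$per_frame$psnr))
  expect_equal(rep$uncropped$mean_ssim, mean(rep$uncropped$per_frame$ssim))
  expect_identical(rep$n_frames, 8)
})

test_that("a perfect forecast scores SSIM 1, capped PSNR and zero FVD", {
  pv <- fix_pvideo15()
  model <- fix_tiny_predictor()
  # forge forecasts whose images equal ground truth, for two "videos"
  forge <- function() {
    fc <- forecast_till_end(model, pv$frames, pv$hpi, n_total = 15)
    for (i in seq_along(fc$entries)) {
      lab <- fc$entries[[i]]$frame_label
      fc$entries[[i]]$image <- pv$frames[, , 1:3, lab]
    }
    fc
  }
  rep <- evaluate_forecast(list(pv$frames, pv$frames), list(forge(), forge()),
                           truncations = c(6L))
  expect_equal(rep$uncropped$mean_ssim, 1)
  expect_equal(rep$uncropped$mean_psnr, 100)
  expect_lt(rep$uncropped$fvd[["t6"]], 1e-6)
})
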