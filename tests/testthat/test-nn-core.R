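# Compute core: convolution oracle, analytic gradients vs finite differences.

# direct convolution oracle in R (same zero padding, odd kernel)
conv2d_oracle <- function(x, w, b, k) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  Cout <- nrow(w)
  p <- (k - 1) / 2
  out <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Cin)) {
      for (dj in 0:(k - 1)) {
        for (di in 0:(k - 1)) {
          wv <- w[co, (ci - 1) * k * k + dj * k + di + 1]
          if (wv == 0) next
          src <- matrix(0, H, W)
          si <- (1 + di - p):(H + di - p)
          sj <- (1 + dj - p):(W + dj - p)
          oki <- si >= 1 & si <= H
          okj <- sj >= 1 & sj <= W
          src[which(oki), which(okj)] <- x[si[oki], sj[okj], ci]
          acc <- acc + wv * src
        }
      }
    }
    out[, , co] <- acc
  }
  out
}

test_that("the GEMM convolution matches a direct R convolution", {
  set.seed(21)
  for (k in c(1, 3, 5)) {
    x <- array(rnorm(10 * 9 * 3), c(10, 9, 3))
    w <- matrix(rnorm(2 * 3 * k * k), 2, 3 * k * k)
    b <- rnorm(2)
    got <- cpp_conv2d(x, w, b, as.integer(k))
    expect_equal(as.vector(got), as.vector(conv2d_oracle(x, w, b, k)),
                 tolerance = 1e-12)
  }
})

fd_grad <- function(lossfun, par, idx, h = 1e-5) {
  vapply(idx, function(i) {
    p1 <- par; p1[i] <- p1[i] + h
    p2 <- par; p2[i] <- p2[i] - h
    (lossfun(p1) - lossfun(p2)) / (2 * h)
  }, numeric(1))
}

rel_err <- function(a, b) max(abs(a - b) / pmax(1e-8, abs(a) + abs(b)))

test_that("FramePredictor analytic gradients match finite differences", {
  cfg <- list(H = 8L, W = 8L, C = 3L, F = 3L, filters = c(2L, 3L, 2L, 2L),
              kernels = c(3L, 3L, 3L, 1L), head_kernel = 3L,
              activation = "tanh")
  sh <- lapply(cpp_fp_shapes(cfg), function(d) c(d[1], d[2]))
  par <- nn_init_params(sh, seed = 1)
  set.seed(2)
  x <- array(runif(8 * 8 * 3 * 3), c(8, 8, 3, 3))
  yf <- array(runif(8 * 8 * 3), c(8, 8, 3))
  yi <- array(runif(8 * 8 * 3), c(8, 8, 3))
  mask <- array(stats::rbinom(8 * 8 * 2, 1, 0.75) / 0.75, c(8, 8, 2))
  for (act in c("tanh", "relu")) {
    cfg$activation <- act
    g <- cpp_fp_run(par, cfg, x, mask, yf, yi, TRUE)$grad
    lf <- function(p) cpp_fp_run(p, cfg, x, mask, yf, yi, FALSE)$loss
    set.seed(3)
    idx <- sample(length(par), 40)
    expect_lt(rel_err(fd_grad(lf, par, idx), g[idx]), 1e-4)
  }
})

test_that("U-Net analytic gradients match finite differences", {
  cfg <- list(H = 16L, W = 16L, Cin = 3L, depth = 2L, base = 3L,
              nclasses = 2L)
  sh <- lapply(cpp_unet_shapes(cfg), function(d) c(d[1], d[2]))
  par <- nn_init_params(sh, seed = 4)
  set.seed(5)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  lab <- matrix(sample(0:1, 256, TRUE), 16, 16)
  g <- cpp_unet_run(par, cfg, x, lab, TRUE)$grad
  lf <- function(p) cpp_unet_run(p, cfg, x, lab, FALSE)$loss
  set.seed(6)
  idx <- sample(length(par), 40)
  expect_lt(rel_err(fd_grad(lf, par, idx), g[idx]), 1e-3)
})

test_that("Adam descends a quadratic", {
  par <- c(5, -3, 2)
  st <- adam_init(3)
  for (i in 1:300) {
    g <- 2 * (par - c(1, 2, 3))
    up <- adam_step(par, g, st, lr = 0.05)
    par <- up$par; st <- up$state
  }
  expect_equal(par, c(1, 2, 3), tolerance = 1e-2)
})

test_that("seeded scoping leaves the global RNG stream untouched", {
  set.seed(99)
  a1 <- runif(1)
  set.seed(99)
  invisible(with_local_seed(5, runif(10)))
  a2 <- runif(1)
  expect_identical(a1, a2)
  expect_identical(with_local_seed(5, rnorm(3)), with_local_seed(5, rnorm(3)))
})
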