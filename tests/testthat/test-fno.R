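# The spectral layers are verified three ways: closed-form oracles on the
# Fourier module, finite differences on every parameter gradient, and
# agreement between the fused C++ training step and the plain R pass.

test_that("fourier module is linear and exact at full spectrum", {
  M <- 9; C <- 3
  k_full <- (M + 1) / 2
  Wre <- array(0, c(2 * k_full - 1, 2 * k_full - 1, C, C))
  for (i in 1:C) Wre[, , i, i] <- 1
  Wim <- array(0, dim(Wre))
  set.seed(4)
  v1 <- array(rnorm(M * M * 2 * C), c(M, M, 2, C))
  v2 <- array(rnorm(M * M * 2 * C), c(M, M, 2, C))
  # identity weights at full modes reproduce the input
  expect_all_close(fourier_module(v1, Wre, Wim, k_full)$out, v1, 1e-10)
  # linearity
  set.seed(5)
  Wre[] <- rnorm(length(Wre)); Wim[] <- rnorm(length(Wim))
  f <- function(v) fourier_module(v, Wre, Wim, k_full)$out
  expect_all_close(f(2 * v1 - 3 * v2), 2 * f(v1) - 3 * f(v2), 1e-9)
  # zero input maps to zero
  expect_all_close(f(array(0, dim(v1))), array(0, dim(v1)), 1e-12)
})

test_that("DC-only truncation reduces to the mode-weight average", {
  M <- 9; C <- 3
  set.seed(6)
  Wre <- array(rnorm(C * C), c(1, 1, C, C))
  Wim <- array(rnorm(C * C), c(1, 1, C, C))
  cc <- rnorm(C)
  v <- array(0, c(M, M, 1, C))
  for (i in 1:C) v[, , 1, i] <- cc[i]
  o <- fourier_module(v, Wre, Wim, 1)$out
  for (oc in 1:C) {
    expected <- sum(cc * Wre[1, 1, , oc])    # real part of the DC algebra
    expect_all_close(o[, , 1, oc], matrix(expected, M, M), 1e-10)
  }
})

test_that("restricted transform agrees with the full FFT on kept modes", {
  M <- 15; k <- 4
  set.seed(7)
  x <- array(rnorm(M * M * 3), c(M, M, 3))
  full <- rpfno:::fft2_stack(x)
  idx <- c(1:k, (M - k + 2):M)
  E <- rpfno:::dft_restricted(M, k)
  restricted <- rpfno:::fwd_transform(x, E)
  expect_all_close(restricted, full[idx, idx, ], 1e-9)
})

test_that("a zero-weight fourier layer outputs sigmoid(0) = 0.5", {
  M <- 9; C <- 3
  z <- array(0, c(2 * 2 - 1, 2 * 2 - 1, C, C))
  v <- array(rnorm(M * M * 2 * C), c(M, M, 2, C))
  fl <- fourier_layer(v, z, z, 2, matrix(0, C, C), numeric(C))
  expect_all_close(fl$out, array(0.5, dim(v)), 1e-12)
  # any weights: outputs strictly inside (0, 1)
  set.seed(8)
  fl2 <- fourier_layer(v, z + rnorm(length(z)), z + rnorm(length(z)), 2,
                       matrix(rnorm(C * C), C, C), rnorm(C))
  expect_true(all(fl2$out > 0 & fl2$out < 1))
})

test_that("forecaster maps 30 frames to 20 frames and checks shapes", {
  m <- fno_init(fno_config(width = 4), seed = 1)
  x <- array(rnorm(29 * 29 * 30), c(29, 29, 30))
  out <- fno_forward(m, x)
  expect_equal(dim(out), c(29, 29, 20))
  expect_error(fno_forward(m, x[, , 1:10]), "expects T = 30")
  # zeroed projection ignores the input entirely
  m0 <- m
  m0$params$proj_W[] <- 0; m0$params$proj_b[] <- 0
  expect_all_close(fno_forward(m0, x), array(0, c(29, 29, 20)), 1e-12)
  # mode count must fit the grid
  expect_error(fno_forward(m, array(0, c(9, 9, 30))), "inadmissible")
  # parameter count does not depend on the grid: the same weights run at
  # 29 and at 17 (mesh independence)
  expect_silent(fno_forward(m, array(rnorm(17 * 17 * 30), c(17, 17, 30))))
})

test_that("every analytic gradient matches finite differences", {
  cfg <- fno_config(num_layers = 2, width = 3, modes = 2, input_steps = 2,
                    horizon = 2)
  m <- fno_init(cfg, seed = 5)
  M <- 7; B <- 2
  set.seed(3)
  x <- array(rnorm(M * M * B * 2), c(M, M, B, 2))
  y <- array(rnorm(M * M * B * 2), c(M, M, B, 2))
  loss_fn <- function(params) {
    mm <- m; mm$params <- params
    mean((forward_pass(mm, x)$out - y)^2)
  }
  fp <- forward_pass(m, x, keep_cache = TRUE)
  grads <- backward_pass(m, fp$cache, 2 * (fp$out - y) / length(y))
  eps <- 1e-6
  for (nm in names(m$params)) {
    ii <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    num <- vapply(ii, function(i) {
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
    }, numeric(1))
    rel <- max(abs(num - grads[[nm]][ii])) / max(1e-8, max(abs(num)))
    expect_lt(rel, 1e-4)
  }
})

test_that("fused training step equals the reference forward/backward", {
  cfg <- fno_config(num_layers = 3, width = 5, modes = 3, input_steps = 4,
                    horizon = 3)
  m <- fno_init(cfg, seed = 6)
  M <- 9; B <- 4
  set.seed(5)
  x <- array(rnorm(M * M * B * 4), c(M, M, B, 4))
  y <- array(rnorm(M * M * B * 3), c(M, M, B, 3))
  fp <- forward_pass(m, x, keep_cache = TRUE)
  diff <- fp$out - y
  grads_r <- backward_pass(m, fp$cache, 2 * diff / length(diff))
  st <- rpfno:::cpp_fno_step(x, y, rpfno:::dft_restricted(M, 3), m$params,
                             M, B, 4L, 3L, 3L, 5L)
  expect_all_close(st$loss, mean(diff^2), 1e-12)
  for (nm in names(grads_r))
    expect_all_close(as.numeric(st$grads[[nm]]),
                     as.numeric(grads_r[[nm]]), 1e-10)
})

test_that("the operator can overfit a single sample", {
  ds <- tiny_dataset()                       # 11x11 grid
  cfg <- fno_config(num_layers = 2, width = 16, modes = 4)
  m <- fno_init(cfg, seed = 9)
  m$normalizer <- fit_rp_normalizer(ds, 1:5)
  g <- rpfno:::gather_batch(ds, 5L, m$normalizer$scale)
  E <- rpfno:::dft_restricted(ds$M, cfg$modes)
  opt <- rpfno:::adam_init(m$params)
  loss <- NA
  for (it in 1:500) {
    st <- rpfno:::cpp_fno_step(g$x, g$y, E, m$params, ds$M, 1L, 30L, 20L,
                               cfg$num_layers, cfg$width)
    upd <- rpfno:::adam_step(m$params, st$grads, opt, 3e-3)
    m$params <- upd$params; opt <- upd$state
    loss <- st$loss
  }
  expect_lt(loss, 1e-3)
})

test_that("frame resizing is exact for linear ramps", {
  ramp <- outer(seq(0, 1, length.out = 29), seq(0, 2, length.out = 29), "+")
  down <- resize_frames(ramp, 15)
  truth <- outer(seq(0, 1, length.out = 15), seq(0, 2, length.out = 15), "+")
  expect_all_close(down, truth, 1e-10)
  expect_all_close(resize_frames(ramp, 29), ramp, 1e-10)
})
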