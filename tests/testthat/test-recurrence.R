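test_that("window concatenation has the documented shape and count", {
  p <- make_subject_profile("s1", "walking", seed = 7)
  s <- generate_motion_stream(p, 20, 30)
  cfg <- encoding_config()
  w <- window_axes(s, cfg)
  expect_equal(nrow(w$values), 15)       # 3 axes x 5 samples
  n <- ncol(s$axes)
  expect_equal(ncol(w$values), floor((n - 5) / 1) + 1)
  # explicit enumeration oracle on a small stream
  short <- sensor_stream((0:9) / 30, matrix(rnorm(30), 3, 10), 30)
  ws <- window_axes(short, cfg)
  expect_equal(ncol(ws$values), 6)
  for (k in 1:6) {
    t_end <- ws$t_index[k]
    expect_equal(ws$values[, k],
                 c(short$axes[1, (t_end - 4):t_end],
                   short$axes[2, (t_end - 4):t_end],
                   short$axes[3, (t_end - 4):t_end]))
  }
  tw1 <- window_axes(short, encoding_config(window_size = 1))
  expect_equal(tw1$values[, 3], unname(short$axes[, 3]))
  expect_error(window_axes(short, encoding_config(window_size = 11)),
               "window_size")
})

test_that("midpoint interpolation doubles the vector minus one", {
  expect_equal(interpolate_window(c(0, 2)), c(0, 1, 2))
  expect_equal(interpolate_window(c(1, 4, 9)), c(1, 2.5, 4, 6.5, 9))
  x <- rnorm(15)
  y <- interpolate_window(x)
  expect_length(y, 29)
  # original entries preserved at odd positions; even-position subsample
  # recovers the original vector exactly
  expect_identical(y[seq(1, 29, 2)], x)
  expect_error(interpolate_window(3), "at least 2")
})

test_that("recurrence plots equal the brute-force distance matrix", {
  expect_equal(recurrence_plot(c(0, 1, 3)),
               matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3))
  expect_equal(recurrence_plot(rep(2, 5)), matrix(0, 5, 5))
  set.seed(1)
  for (M in c(2, 5, 9, 15, 29)) {
    x <- rnorm(M)
    Y <- recurrence_plot(x)
    brute <- matrix(0, M, M)
    for (i in 1:M) for (j in 1:M) brute[i, j] <- sqrt((x[i] - x[j])^2)
    expect_all_close(Y, brute)
    expect_identical(Y, t(Y))
    expect_true(all(diag(Y) == 0))
    # triangle-type bound |Y[i,k] - Y[k,j]| <= Y[i,j]
    for (k in 1:M)
      expect_true(all(abs(outer(Y[, k], Y[k, ], "-")) <= Y + 1e-12))
  }
})

test_that("recurrence plots lose sign and offset information", {
  x <- rnorm(29)
  expect_all_close(recurrence_plot(-x + 5), recurrence_plot(x))
})

test_that("cross recurrence plots compare two sensors", {
  expect_equal(cross_recurrence_plot(c(0, 1), c(2, 0)),
               matrix(c(2, 1, 0, 1), 2, 2))
  x <- rnorm(9)
  expect_all_close(cross_recurrence_plot(x, x), recurrence_plot(x))
  set.seed(2)
  y <- rnorm(9)
  C <- cross_recurrence_plot(x, y)
  brute <- matrix(0, 9, 9)
  for (i in 1:9) for (j in 1:9) brute[i, j] <- abs(x[i] - y[j])
  expect_all_close(C, brute)
  expect_error(cross_recurrence_plot(x, y[1:5]), "lengths differ")
})

test_that("gyro+accelerometer fusion yields 29x29 cross-recurrence frames", {
  p <- make_subject_profile("s1", "walking", seed = 7)
  g <- generate_motion_stream(p, 10, 30)
  a <- generate_motion_stream(p, 10, 30, sensor_kind = "accelerometer")
  enc <- encode_stream(g, encoding_config(), accel = a)
  expect_equal(dim(enc$frames)[1:2], c(29, 29))
  # CRP is not symmetric in general
  expect_gt(max(abs(enc$frames[, , 10] - t(enc$frames[, , 10]))), 0)
})

test_that("sample assembly counts and alignment are exact", {
  p <- make_subject_profile("s1", "walking", seed = 7)
  s <- generate_motion_stream(p, 60, 30)
  ds <- encode_dataset(s, encoding_config(), subject_id = "s1")
  expect_equal(dim(ds$frames)[3], 1796)        # 1800 - 5 + 1 windows
  expect_equal(n_samples(ds), 1747)            # 1796 - 30 - 20 + 1
  sm <- get_sample(ds, 10)
  expect_equal(dim(sm$input_frames), c(29, 29, 30))
  expect_equal(dim(sm$target_frames), c(29, 29, 20))
  expect_equal(dim(sm$target_signal), c(3, 20))
  # target signal is the raw samples at the target frames' end indices
  expect_identical(sm$target_signal, s$axes[, sm$t_index])
  # input spans T frames = 1 s at 30 Hz with stride 1
  first_in <- ds$t_index[10]; last_in <- ds$t_index[10 + 30 - 1]
  expect_equal(last_in - first_in + 1, 30)
  # exactly T + T_hat frames (54 samples -> 50 windows) give one sample
  short <- sensor_stream((0:53) / 30, matrix(rnorm(162), 3, 54), 30)
  expect_equal(n_samples(encode_dataset(short, encoding_config())), 1)
  tooshort <- sensor_stream((0:52) / 30, matrix(rnorm(159), 3, 53), 30)
  expect_error(encode_dataset(tooshort, encoding_config()), "at least")
})

test_that("dataset subsetting and pooling preserve sample content", {
  ds <- tiny_dataset()
  sub <- subset_dataset(ds, 11, 40)
  expect_equal(n_samples(sub), 30)
  expect_identical(get_sample(sub, 1)$input_frames,
                   get_sample(ds, 11)$input_frames)
  pooled <- concat_datasets(list(sub, subset_dataset(ds, 61, 80)))
  expect_equal(n_samples(pooled), 50)
  expect_identical(get_sample(pooled, 31)$target_frames,
                   get_sample(ds, 61)$target_frames)
  # no pooled sample spans the recording boundary: frame spans stay
  # within one source block
  span <- pooled$cfg$input_steps + pooled$cfg$horizon
  block1 <- dim(sub$frames)[3]
  starts <- pooled$starts
  expect_true(all(starts + span - 1 <= block1 | starts > block1))
})
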