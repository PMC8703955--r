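test_that("subject profiles are deterministic and seed-dependent", {
  a <- make_subject_profile("s1", "walking", seed = 7)
  b <- make_subject_profile("s1", "walking", seed = 7)
  expect_identical(a, b)
  c <- make_subject_profile("s2", "walking", seed = 8)
  expect_false(isTRUE(all.equal(a$fundamental_freq, c$fundamental_freq)))
  expect_true(a$fundamental_freq >= 1.4 && a$fundamental_freq <= 2.0)
  r <- make_subject_profile("s3", "running", seed = 9)
  expect_true(r$fundamental_freq >= 2.4 && r$fundamental_freq <= 3.0)
  expect_error(make_subject_profile("s4", "swimming", seed = 1),
               "motion_kind")
})

test_that("cohorts keep pairwise stride-frequency gaps", {
  for (seed in c(1, 11, 101)) {
    coh <- make_subject_cohort(6, "walking", seed = seed)
    f <- vapply(coh, `[[`, numeric(1), "fundamental_freq")
    d <- abs(outer(f, f, "-")); diag(d) <- Inf
    expect_gte(min(d), 0.05)
  }
})

test_that("stream generation matches the harmonic model", {
  p <- make_subject_profile("s1", "walking", seed = 7)
  s <- generate_motion_stream(p, 60, 30)
  expect_equal(ncol(s$axes), 1800)              # 30 Hz x 60 s
  expect_equal(diff(s$timestamps), rep(1 / 30, 1799), tolerance = 1e-12)
  expect_identical(s$axes, generate_motion_stream(p, 60, 30)$axes)
  # noiseless single harmonic is an exact unit sinusoid
  up <- unit_profile(f0 = 1)
  su <- generate_motion_stream(up, 4, 30)
  t <- (0:119) / 30
  expect_all_close(su$axes[1, ], sin(2 * pi * t))
  # different realizations share the waveform, not the noise
  pn <- make_subject_profile("s1", "walking", seed = 7, noise_sd = 0.05)
  r1 <- generate_motion_stream(pn, 5, 30, realization = 1)
  r2 <- generate_motion_stream(pn, 5, 30, realization = 2)
  expect_false(identical(r1$axes, r2$axes))
  expect_lt(max(abs(r1$axes - r2$axes)), 6 * 0.05 * 2)
})

test_that("periodicity and spectral structure of generated streams", {
  up <- unit_profile(f0 = 1.5)
  s <- generate_motion_stream(up, 20, 30)
  # noiseless stream is exactly periodic at the fundamental: 1.5 Hz at
  # 30 Hz puts one period at 20 samples
  expect_all_close(s$axes[, 1:100], s$axes[, 21:120], tol = 1e-9)
  # autocorrelation oracle: dominant lag near rate / f0
  pn <- unit_profile(f0 = 1.8, noise = 0.05)
  sn <- generate_motion_stream(pn, 30, 30)
  ac <- stats::acf(sn$axes[1, ], lag.max = 25, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[5:25]) + 4, round(30 / 1.8), tolerance = 1)
  # spectral peak sits at a harmonic of the fundamental
  p <- make_subject_profile("s1", "walking", seed = 3)
  sp <- generate_motion_stream(p, 20, 30)
  for (a in 1:3) {
    mag <- Mod(stats::fft(sp$axes[a, ]))[2:300]
    peak_hz <- which.max(mag) / 20            # bins at 1/20 Hz
    ratio <- peak_hz / p$fundamental_freq
    expect_lt(abs(ratio - round(ratio)), 0.05)
  }
})

test_that("fall injection produces a labelled burst-then-rest transient", {
  p <- make_subject_profile("s1", "walking", seed = 7)
  s <- generate_motion_stream(p, 20, 30)
  expect_error(inject_fall(s, onset_s = 25), "out of range")
  fa <- inject_fall(s, onset_s = 16, seed = 3)
  ann <- fa$annotation
  expect_equal(length(ann$label_track), ncol(s$axes))
  expect_equal(sum(ann$label_track == "fall"),
               ncol(s$axes) - ann$onset_index + 1)
  # burst amplitude >= 3x the pre-onset per-axis maximum
  pre_max <- apply(abs(s$axes[, 1:(ann$onset_index - 1)]), 1, max)
  burst <- fa$stream$axes[, ann$onset_index:
                            (ann$onset_index + ann$burst_duration - 1)]
  expect_true(all(apply(abs(burst), 1, max) >= 3 * pre_max))
  # recurrence frames overlapping the burst dwarf pre-onset frames
  enc <- encode_stream(fa$stream, encoding_config())
  burst_frames <- which(enc$t_index >= ann$onset_index &
                          enc$t_index < ann$onset_index + ann$burst_duration)
  pre_frames <- which(enc$t_index < ann$onset_index)
  max_burst <- max(enc$frames[, , burst_frames])
  med_pre <- stats::median(apply(enc$frames[, , pre_frames], 3, max))
  expect_gte(max_burst, 3 * med_pre)
})
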