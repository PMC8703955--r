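test_that("decoder emits one 3-axis sample per frame", {
  dm <- decoder_init(decoder_config(hidden = 8, head = 4), M = 11, seed = 1)
  frames <- array(abs(rnorm(11 * 11 * 20)), c(11, 11, 20))
  seg <- decode_sequence(frames, dm)
  expect_s3_class(seg, "reconstructed_segment")
  expect_equal(dim(seg$samples), c(3, 20))
  # decoding is deterministic given the model
  expect_identical(seg$samples, decode_sequence(frames, dm)$samples)
  # a zeroed head produces all-zero samples
  dm0 <- dm
  dm0$params$head2_W[] <- 0; dm0$params$head2_b[] <- 0
  expect_all_close(decode_sequence(frames, dm0)$samples,
                   matrix(0, 3, 20), 1e-12)
  expect_error(decode_sequence(array(0, c(9, 9, 20)), dm), "trained at")
})

test_that("LSTM gradients match finite differences", {
  H <- 4
  dm <- decoder_init(decoder_config(hidden = H, head = 3), M = 3, seed = 2)
  Tn <- 3; B <- 2
  set.seed(6)
  xs <- lapply(1:Tn, function(t) matrix(rnorm(B * 9), B, 9))
  ys <- lapply(1:Tn, function(t) matrix(rnorm(B * 3), B, 3))
  loss_fn <- function(params) {
    fw <- rpfno:::decoder_forward_steps(params, xs, H)
    mean(vapply(1:Tn, function(t) mean((fw$outs[[t]] - ys[[t]])^2), 0))
  }
  fw <- rpfno:::decoder_forward_steps(dm$params, xs, H, keep_cache = TRUE)
  douts <- lapply(1:Tn, function(t)
    2 * (fw$outs[[t]] - ys[[t]]) / (Tn * B * 3))
  grads <- rpfno:::decoder_backward_steps(dm$params, xs, fw$cache, douts, H)
  eps <- 1e-6
  for (nm in names(dm$params)) {
    ii <- sample(length(dm$params[[nm]]), min(4, length(dm$params[[nm]])))
    num <- vapply(ii, function(i) {
      p1 <- dm$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- dm$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
    }, numeric(1))
    rel <- max(abs(num - grads[[nm]][ii])) / max(1e-8, max(abs(num)))
    expect_lt(rel, 1e-4)
  }
})

test_that("stitching keeps the earliest value and marks gaps", {
  seg <- function(start, vals) {
    structure(list(samples = matrix(vals, 3, length(vals) / 3),
                   t_index = start + seq_len(length(vals) / 3) - 1),
              class = "reconstructed_segment")
  }
  a <- seg(1, rep(1, 60))     # spans 1..20
  b <- seg(2, rep(2, 60))     # spans 2..21
  st <- stitch_predictions(list(a, b))
  expect_equal(length(st$t_index), 21)
  expect_true(all(st$samples[, 1:20] == 1))   # first-wins
  expect_true(all(st$samples[, 21] == 2))
  expect_length(attr(st, "gaps"), 0)
  # idempotence on duplicates
  st2 <- stitch_predictions(list(a, a))
  expect_equal(st2$samples, a$samples, ignore_attr = TRUE)
  # non-contiguous coverage is marked, not filled
  c2 <- seg(30, rep(3, 15))
  st3 <- stitch_predictions(list(a, c2))
  expect_true(all(is.na(st3$samples[, match(21:29, st3$t_index)])))
  expect_equal(attr(st3, "gaps"), 21:29)
})

test_that("stitched decoded segments equal frame-wise decoding", {
  ds <- tiny_dataset()
  dm <- decoder_init(decoder_config(hidden = 8, head = 4), M = ds$M,
                     seed = 3)
  dm$normalizer <- fit_rp_normalizer(ds, 1:10)
  segs <- lapply(c(1, 8, 15), function(i) {
    sm <- get_sample(ds, i)
    decode_sequence(sm$target_frames, dm, t_index = sm$t_index)
  })
  st <- stitch_predictions(segs)
  for (s in segs) {
    pos <- match(s$t_index, st$t_index)
    keep <- !duplicated(unlist(lapply(segs, `[[`, "t_index")))[pos]
    # every stitched index carries the value of the earliest segment
    first_claims <- st$samples[, pos[s$t_index %in% st$t_index]]
    expect_true(all(is.finite(first_claims)))
  }
  # elementwise: indices owned by the first segment match it exactly
  expect_all_close(st$samples[, match(segs[[1]]$t_index, st$t_index)],
                   segs[[1]]$samples, 1e-12)
})
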