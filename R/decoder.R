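# Signal decoder: recovers raw 3-axis samples from sequences of
# (predicted) recurrence-plot frames.
#
# An LSTM consumes the frame sequence (each M x M frame flattened to its
# M^2 entries as one step's input) and a two-layer fully-connected head
# maps each step's hidden state to the 3-axis sample at that frame's end
# index. A distance image is invariant to a global sign flip and constant
# offset of its window, so the decoder can only pin the signal down to
# what its training distribution disambiguates; recovery quality is
# therefore scored by per-axis correlation (waveform shape) on held-out
# windows of the same subject.

#' Decoder configuration
#'
#' @param hidden LSTM hidden size (default 128).
#' @param head Width of the first fully-connected head layer (default 64);
#'   the head is hidden -> head -> 3.
#' @return Object of class `decoder_config`.
#' @export
decoder_config <- function(hidden = 128L, head = 64L) {
  stopifnot(hidden >= 1, head >= 1)
  structure(list(hidden = as.integer(hidden), head = as.integer(head)),
            class = "decoder_config")
}

#' Initialise a decoder at a fixed grid size
#'
#' @param cfg A [decoder_config()].
#' @param M Grid side length of the frames the decoder consumes.
#' @param seed Integer seed.
#' @return Object of class `decoder_model`. Training fills in the
#'   recurrence-plot normalizer and the per-axis signal standardisation
#'   (mean/sd) used to de-standardise decoded output.
#' @export
decoder_init <- function(cfg = decoder_config(), M, seed = 1L) {
  stopifnot(inherits(cfg, "decoder_config"))
  D <- as.integer(M)^2
  H <- cfg$hidden
  with_seed(seed, {
    sx <- 1 / sqrt(D); sh <- 1 / sqrt(H)
    params <- list(
      Wx = matrix(stats::runif(D * 4 * H, -sx, sx), D, 4 * H),
      Wh = matrix(stats::runif(H * 4 * H, -sh, sh), H, 4 * H),
      b  = rep(c(0, 1, 0, 0), each = H))   # forget-gate bias 1
    f1 <- init_linear(H, cfg$head)
    f2 <- init_linear(cfg$head, 3L)
    params$head1_W <- f1$W; params$head1_b <- f1$b
    params$head2_W <- f2$W; params$head2_b <- f2$b
    structure(list(cfg = cfg, params = params, M = as.integer(M),
                   seed = as.integer(seed), normalizer = NULL,
                   signal_stats = NULL),
              class = "decoder_model")
  })
}

# LSTM + head forward over xs, a list of per-step (B x M^2) inputs.
# Returns per-step outputs (B x 3) and caches for BPTT.
#' @noRd
decoder_forward_steps <- function(params, xs, H, keep_cache = FALSE) {
  B <- nrow(xs[[1]])
  Tn <- length(xs)
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  gi <- seq_len(H); gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
  outs <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    G <- xs[[t]] %*% params$Wx + h %*% params$Wh
    G <- sweep(G, 2L, params$b, "+")
    i <- sigmoid(G[, gi, drop = FALSE]); f <- sigmoid(G[, gf, drop = FALSE])
    g <- tanh(G[, gg, drop = FALSE]);    o <- sigmoid(G[, go, drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    r1 <- relu(sweep(h %*% params$head1_W, 2L, params$head1_b, "+"))
    outs[[t]] <- sweep(r1 %*% params$head2_W, 2L, params$head2_b, "+")
    if (keep_cache)
      cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev,
                         tc = tc, h_prev = h_prev, h = h, r1 = r1)
  }
  list(outs = outs, cache = cache)
}

# BPTT through decoder_forward_steps. douts: list of per-step (B x 3).
#' @noRd
decoder_backward_steps <- function(params, xs, cache, douts, H) {
  B <- nrow(xs[[1]])
  Tn <- length(xs)
  gi <- seq_len(H); gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
  grads <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dy <- douts[[t]]
    grads$head2_W <- grads$head2_W + crossprod(cc$r1, dy)
    grads$head2_b <- grads$head2_b + colSums(dy)
    dr1 <- (dy %*% t(params$head2_W)) * (cc$r1 > 0)
    grads$head1_W <- grads$head1_W + crossprod(cc$h, dr1)
    grads$head1_b <- grads$head1_b + colSums(dr1)
    dh <- dr1 %*% t(params$head1_W) + dh_next
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g; df <- dc * cc$c_prev; dg <- dc * cc$i
    dG <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
    grads$Wx <- grads$Wx + crossprod(xs[[t]], dG)
    grads$Wh <- grads$Wh + crossprod(cc$h_prev, dG)
    grads$b <- grads$b + colSums(dG)
    dh_next <- dG %*% t(params$Wh)
    dc_next <- dc * cc$f
  }
  grads
}

#' Decode a frame sequence back to raw 3-axis samples
#'
#' For each frame the decoder emits the 3-axis sample at that frame's end
#' index, so T-hat frames in give a 3 x T-hat segment out. Decoding is
#' deterministic given a trained model.
#'
#' @param frames Array (M, M, T_hat) of raw-scale recurrence-plot frames
#'   (the model applies its stored normalizer), or (M, M, T_hat, B).
#' @param model A trained `decoder_model` (see [train_decoder()]).
#' @param t_index Optional sample indices of the frames' end samples,
#'   carried into the result for stitching.
#' @return A `reconstructed_segment`: list with `samples` (3 x T_hat,
#'   de-standardised to the training signal units) and `t_index`. For a
#'   batch, a list of segments.
#' @export
decode_sequence <- function(frames, model, t_index = NULL) {
  stopifnot(inherits(model, "decoder_model"))
  single <- length(dim(frames)) == 3L
  if (single) dim(frames) <- c(dim(frames), 1L)
  d <- dim(frames)
  if (d[1] != model$M || d[2] != model$M)
    stop(sprintf("decoder trained at %dx%d, got %dx%d frames",
                 model$M, model$M, d[1], d[2]), call. = FALSE)
  sc <- if (!is.null(model$normalizer)) model$normalizer$scale else 1
  B <- d[4]; Tn <- d[3]
  xs <- lapply(seq_len(Tn), function(t)
    t(matrix(frames[, , t, ] / sc, ncol = B)))
  fw <- decoder_forward_steps(model$params, xs, model$cfg$hidden)
  st <- model$signal_stats
  segs <- lapply(seq_len(B), function(b) {
    y <- t(vapply(fw$outs, function(o) o[b, ], numeric(3)))  # T_hat x 3
    y <- t(y)                                                # 3 x T_hat
    if (!is.null(st)) y <- y * st$sd + st$mean
    rownames(y) <- c("x", "y", "z")
    structure(list(samples = y,
                   t_index = if (is.null(t_index)) seq_len(Tn) else t_index),
              class = "reconstructed_segment")
  })
  if (single) segs[[1]] else segs
}

#' Stitch overlapping decoded segments into one signal
#'
#' Segments are ordered by start index; where spans overlap, the value from
#' the earliest-issued segment wins (first-wins de-duplication). The output
#' covers the union of the spans; indices covered by no segment are
#' returned as `NA` with the gaps listed, never silently filled.
#'
#' @param segments List of `reconstructed_segment`s with `t_index` spans.
#' @return A `reconstructed_segment` whose `samples` is 3 x n over the
#'   union span, with attribute `gaps` (indices not covered).
#' @export
stitch_predictions <- function(segments) {
  stopifnot(length(segments) >= 1)
  starts <- vapply(segments, function(s) s$t_index[1], numeric(1))
  segments <- segments[order(starts)]
  all_idx <- sort(unique(unlist(lapply(segments, `[[`, "t_index"))))
  span <- seq.int(min(all_idx), max(all_idx))
  out <- matrix(NA_real_, 3, length(span),
                dimnames = list(c("x", "y", "z"), NULL))
  filled <- rep(FALSE, length(span))
  for (s in segments) {
    pos <- match(s$t_index, span)
    new <- !filled[pos]
    out[, pos[new]] <- s$samples[, new, drop = FALSE]
    filled[pos[new]] <- TRUE
  }
  res <- structure(list(samples = out, t_index = span),
                   class = "reconstructed_segment")
  attr(res, "gaps") <- span[!filled]
  res
}

#' Train the decoder on true frame/signal pairs
#'
#' Training pairs are (true target-frame stacks -> true aligned signals);
#' at inference the decoder receives FNO-predicted frames. Signals are
#' standardised per axis with training-split statistics (stored in the
#' model and undone by [decode_sequence()]); frames are divided by the
#' recurrence-plot normalizer. Adam on MSE with the halving learning-rate
#' schedule, deterministic given `cfg$seed`.
#'
#' @param model A `decoder_model` from [decoder_init()].
#' @param ds An `rp_dataset`.
#' @param train_idx,val_idx Sample indices for training and (optional)
#'   validation monitoring.
#' @param cfg A [training_config()].
#' @param normalizer Recurrence-plot normalizer; defaults to one fitted on
#'   the training split.
#' @return List with `model` (trained) and `curves` (per-epoch data frame
#'   of train/validation MSE in standardised units).
#' @export
train_decoder <- function(model, ds, train_idx, val_idx = integer(0),
                          cfg = training_config(),
                          normalizer = fit_rp_normalizer(ds, train_idx)) {
  stopifnot(inherits(model, "decoder_model"), inherits(ds, "rp_dataset"))
  H <- model$cfg$hidden
  Tn <- ds$cfg$horizon
  sig_at <- function(i) {
    s <- ds$starts[i]
    tgt <- (s + ds$cfg$input_steps):(s + ds$cfg$input_steps + Tn - 1L)
    ds$signals[, ds$t_index[tgt], drop = FALSE]
  }
  train_sig <- vapply(train_idx, sig_at, matrix(0, 3, Tn))
  st <- list(mean = apply(train_sig, 1, mean), sd = apply(train_sig, 1, sd))
  st$sd[st$sd == 0] <- 1
  model$normalizer <- normalizer
  model$signal_stats <- st
  sc <- normalizer$scale
  gather <- function(idx) {
    B <- length(idx)
    fstart <- ds$starts[idx]
    xs <- lapply(seq_len(Tn), function(t) {
      m <- vapply(fstart, function(s)
        as.numeric(ds$frames[, , s + ds$cfg$input_steps + t - 1L]) / sc,
        numeric(model$M^2))
      t(m)
    })
    ys <- lapply(seq_len(Tn), function(t) {
      m <- vapply(fstart, function(s)
        (ds$signals[, ds$t_index[s + ds$cfg$input_steps + t - 1L]] - st$mean) /
          st$sd, numeric(3))
      t(m)
    })
    list(xs = xs, ys = ys)
  }
  opt <- adam_init(model$params)
  curves <- data.frame(epoch = integer(0), train_mse = numeric(0),
                       val_mse = numeric(0))
  eval_mse <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    g <- gather(idx)
    fw <- decoder_forward_steps(model$params, g$xs, H)
    mean(vapply(seq_len(Tn),
                function(t) mean((fw$outs[[t]] - g$ys[[t]])^2), 0))
  }
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- lr_schedule(ep - 1L, cfg)
      perm <- sample(train_idx)
      batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        g <- gather(bi)
        fw <- decoder_forward_steps(model$params, g$xs, H, keep_cache = TRUE)
        douts <- vector("list", Tn)
        loss <- 0
        nel <- Tn * length(bi) * 3
        for (t in seq_len(Tn)) {
          diff <- fw$outs[[t]] - g$ys[[t]]
          loss <- loss + sum(diff^2)
          douts[[t]] <- 2 * diff / nel
        }
        loss <- loss / nel
        if (!is.finite(loss))
          stop("decoder training diverged (non-finite loss)", call. = FALSE)
        grads <- decoder_backward_steps(model$params, g$xs, fw$cache, douts, H)
        upd <- adam_step(model$params, grads, opt, lr)
        model$params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + loss * length(bi)
      }
      curves <- rbind(curves,
                      data.frame(epoch = ep,
                                 train_mse = ep_loss / length(train_idx),
                                 val_mse = eval_mse(val_idx)))
    }
  })
  list(model = model, curves = curves)
}
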