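# Convolutional baseline forecaster, structured to match the FNO: the
# spectral layers are replaced by 5x5 same-padded convolutions (stride 1,
# ReLU after every layer except the final one) and the projection by three
# fully-connected layers. Unlike the FNO, the dense head ties the model to
# the grid size it was trained at: it cannot run at any other resolution.

#' CNN baseline configuration
#'
#' Four convolutional layers (kernel 5, stride 1, zero padding so the
#' spatial size never changes) followed by three fully-connected layers
#' mapping the flattened feature map to the T-hat x M x M forecast.
#'
#' @param num_conv Number of convolution layers (default 4).
#' @param channels Feature channels per conv layer (default 16).
#' @param kernel Convolution kernel size (default 5).
#' @param fc_width Widths of the two hidden fully-connected layers.
#' @param input_steps Input frames T (default 30).
#' @param horizon Forecast frames T-hat (default 20).
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(num_conv = 4L, channels = 16L, kernel = 5L,
                       fc_width = c(128L, 128L),
                       input_steps = 30L, horizon = 20L) {
  stopifnot(num_conv >= 1, channels >= 1, kernel >= 1, kernel %% 2 == 1,
            length(fc_width) == 2, input_steps >= 1, horizon >= 1)
  structure(list(num_conv = as.integer(num_conv),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 fc_width = as.integer(fc_width),
                 input_steps = as.integer(input_steps),
                 horizon = as.integer(horizon)),
            class = "cnn_config")
}

#' Initialise the CNN baseline at a fixed grid size
#'
#' @param cfg A [cnn_config()].
#' @param M Grid side length the model is built for (the dense head is
#'   dimensioned for it; inputs of any other size are rejected).
#' @param seed Integer seed.
#' @return Object of class `cnn_model`.
#' @export
cnn_init <- function(cfg = cnn_config(), M, seed = 1L) {
  stopifnot(inherits(cfg, "cnn_config"))
  kk <- cfg$kernel^2
  with_seed(seed, {
    params <- list()
    cin <- cfg$input_steps
    for (n in seq_len(cfg$num_conv)) {
      lin <- init_linear(kk * cin, cfg$channels)
      params[[paste0("conv_W_", n)]] <- array(lin$W,
                                              c(kk, cin, cfg$channels))
      params[[paste0("conv_b_", n)]] <- lin$b
      cin <- cfg$channels
    }
    d_in <- M * M * cfg$channels
    f1 <- init_linear(d_in, cfg$fc_width[1])
    f2 <- init_linear(cfg$fc_width[1], cfg$fc_width[2])
    f3 <- init_linear(cfg$fc_width[2], cfg$horizon * M * M)
    params$fc1_W <- f1$W; params$fc1_b <- f1$b
    params$fc2_W <- f2$W; params$fc2_b <- f2$b
    params$fc3_W <- f3$W; params$fc3_b <- f3$b
    structure(list(cfg = cfg, params = params, M = as.integer(M),
                   seed = as.integer(seed), normalizer = NULL,
                   encoding = NULL),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d conv (k=%d, %d ch) + 3 FC @ %dx%d grid, T = %d -> T_hat = %d, %d parameters\n",
              x$cfg$num_conv, x$cfg$kernel, x$cfg$channels, x$M, x$M,
              x$cfg$input_steps, x$cfg$horizon, n_params(x)))
  invisible(x)
}

# Same-padded convolution of a channel-last (M, M, B, Cin) state,
# implemented as a sum of shifted pointwise products (one matmul per
# kernel offset; no reshuffles needed with the batch dim before channels).
#' @noRd
conv_forward <- function(v, W, b) {
  d <- dim(v)
  M <- d[1]; B <- d[3]; Cin <- d[4]
  kk <- dim(W)[1]; kern <- as.integer(sqrt(kk)); pad <- (kern - 1L) %/% 2L
  Cout <- dim(W)[3]
  Mp <- M + 2L * pad
  vp <- array(0, c(Mp, Mp, B, Cin))
  vp[pad + seq_len(M), pad + seq_len(M), , ] <- v
  ym <- matrix(rep(b, each = M * M * B), M * M * B, Cout)
  o <- 0L
  for (db in 0:(kern - 1L)) for (da in 0:(kern - 1L)) {
    o <- o + 1L
    xs <- vp[da + seq_len(M), db + seq_len(M), , , drop = FALSE]
    ym <- ym + matrix(xs, ncol = Cin) %*% matrix(W[o, , ], Cin, Cout)
  }
  array(ym, c(M, M, B, Cout))
}

#' @noRd
conv_backward <- function(v, W, dy) {
  d <- dim(v)
  M <- d[1]; B <- d[3]; Cin <- d[4]
  kk <- dim(W)[1]; kern <- as.integer(sqrt(kk)); pad <- (kern - 1L) %/% 2L
  Cout <- dim(W)[3]
  Mp <- M + 2L * pad
  vp <- array(0, c(Mp, Mp, B, Cin))
  vp[pad + seq_len(M), pad + seq_len(M), , ] <- v
  dym <- matrix(dy, ncol = Cout)
  dW <- array(0, dim(W))
  dvp <- array(0, c(Mp, Mp, B, Cin))
  o <- 0L
  for (db in 0:(kern - 1L)) for (da in 0:(kern - 1L)) {
    o <- o + 1L
    ra <- da + seq_len(M); rb <- db + seq_len(M)
    xs <- vp[ra, rb, , , drop = FALSE]
    dW[o, , ] <- crossprod(matrix(xs, ncol = Cin), dym)
    dvp[ra, rb, , ] <- dvp[ra, rb, , , drop = FALSE] +
      array(dym %*% t(matrix(W[o, , ], Cin, Cout)), c(M, M, B, Cin))
    }
  list(dW = dW, db = colSums(dym),
       dv = dvp[pad + seq_len(M), pad + seq_len(M), , , drop = FALSE])
}

#' Forward pass of the CNN baseline
#'
#' @param model A `cnn_model`.
#' @param x Input frames (M, M, T) or (M, M, T, B) at the model's training
#'   grid size; any other size is rejected (the dense head is
#'   size-specific — the baseline has no mesh invariance).
#' @return Predicted frames (M, M, T_hat[, B]).
#' @export
cnn_forward <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  single <- length(dim(x)) == 3L
  x <- if (single) array(x, c(dim(x)[1:2], 1L, dim(x)[3]))
       else aperm(x, c(1, 2, 4, 3))
  out <- forward_pass(model, x)$out
  if (single) array(out, dim(out)[c(1, 2, 4)]) else aperm(out, c(1, 2, 4, 3))
}

#' @keywords internal
#' @export
forward_pass.cnn_model <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg
  d <- dim(x)
  if (d[1] != model$M || d[2] != model$M)
    stop(sprintf("CNN trained at %dx%d cannot run on a %dx%d grid",
                 model$M, model$M, d[1], d[2]), call. = FALSE)
  if (d[4] != cfg$input_steps)
    stop(sprintf("input has %d frames, model expects T = %d",
                 d[4], cfg$input_steps), call. = FALSE)
  p <- model$params
  M <- model$M; B <- d[3]
  cache <- if (keep_cache) list(x = x, conv = vector("list", cfg$num_conv))
  v <- x
  for (n in seq_len(cfg$num_conv)) {
    z <- conv_forward(v, p[[paste0("conv_W_", n)]], p[[paste0("conv_b_", n)]])
    a <- relu(z)
    if (keep_cache) cache$conv[[n]] <- list(v_in = v, mask = z > 0)
    v <- a
  }
  f0 <- matrix(aperm(v, c(3, 1, 2, 4)), nrow = B)    # B x (M^2 C)
  h1 <- relu(sweep(f0 %*% p$fc1_W, 2L, p$fc1_b, "+"))
  h2 <- relu(sweep(h1 %*% p$fc2_W, 2L, p$fc2_b, "+"))
  o  <- sweep(h2 %*% p$fc3_W, 2L, p$fc3_b, "+")      # B x (M^2 T_hat)
  out <- aperm(array(o, c(B, M, M, cfg$horizon)), c(2, 3, 1, 4))
  if (keep_cache) {
    cache$f0 <- f0; cache$h1 <- h1; cache$h2 <- h2
  }
  list(out = out, cache = cache)
}

#' @keywords internal
#' @export
backward_pass.cnn_model <- function(model, cache, dout) {
  cfg <- model$cfg
  p <- model$params
  M <- model$M; B <- dim(dout)[3]
  grads <- list()
  do_m <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = B)  # B x (M^2 T_hat)
  grads$fc3_W <- crossprod(cache$h2, do_m); grads$fc3_b <- colSums(do_m)
  dh2 <- (do_m %*% t(p$fc3_W)) * (cache$h2 > 0)
  grads$fc2_W <- crossprod(cache$h1, dh2); grads$fc2_b <- colSums(dh2)
  dh1 <- (dh2 %*% t(p$fc2_W)) * (cache$h1 > 0)
  grads$fc1_W <- crossprod(cache$f0, dh1); grads$fc1_b <- colSums(dh1)
  df0 <- dh1 %*% t(p$fc1_W)
  dv <- aperm(array(df0, c(B, M, M, cfg$channels)), c(2, 3, 1, 4))
  for (n in rev(seq_len(cfg$num_conv))) {
    cc <- cache$conv[[n]]
    dz <- dv * cc$mask
    cb <- conv_backward(cc$v_in, p[[paste0("conv_W_", n)]], dz)
    grads[[paste0("conv_W_", n)]] <- cb$dW
    grads[[paste0("conv_b_", n)]] <- cb$db
    dv <- cb$dv
  }
  grads
}
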