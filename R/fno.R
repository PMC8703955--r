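# Fourier neural operator forecaster.
#
# The operator maps a stack of T recurrence-plot frames (treated as T
# channels per grid point) to T-hat forecast frames: a pointwise linear
# lift to `width` channels, N Fourier layers, and a pointwise linear
# projection. Each Fourier layer adds a spectral branch -- 2-D FFT, complex
# mixing of the retained low-frequency modes across channels, inverse FFT --
# to a pointwise linear branch and applies a sigmoid. Because the spectral
# weights live on frequency indices rather than grid points, the parameter
# count is independent of the grid size M and a trained model evaluates at
# other resolutions without retraining (mesh invariance).

#' Fourier neural operator configuration
#'
#' @param num_layers Number of Fourier layers N (default 4).
#' @param width Channels of the lifted representation (default 32).
#' @param modes Retained frequencies k per grid axis: the spectral branch
#'   mixes all modes with |p| < k and |q| < k (default 8, which keeps the
#'   17/23/29 grids of the mesh-invariance experiment admissible).
#' @param input_steps Input frames T (default 30).
#' @param horizon Forecast frames T-hat (default 20).
#' @return Object of class `fno_config`.
#' @export
fno_config <- function(num_layers = 4L, width = 32L, modes = 8L,
                       input_steps = 30L, horizon = 20L) {
  stopifnot(num_layers >= 1, width >= 1, modes >= 1,
            input_steps >= 1, horizon >= 1)
  structure(list(num_layers = as.integer(num_layers),
                 width = as.integer(width), modes = as.integer(modes),
                 input_steps = as.integer(input_steps),
                 horizon = as.integer(horizon)),
            class = "fno_config")
}

# 1-based FFT bin indices of the retained frequencies {0,...,k-1} and
# {-(k-1),...,-1} on an axis of length M.
#' @noRd
mode_index <- function(M, k) {
  if (2L * k - 1L > M)
    stop(sprintf(
      "modes k = %d inadmissible for grid size M = %d; need k <= %d",
      k, M, (M + 1L) %/% 2L), call. = FALSE)
  c(seq_len(k), if (k > 1L) seq.int(M - k + 2L, M))
}

# Because every mode outside the retained (2k-1)^2 block is zeroed, the
# forward and inverse transforms reduce to multiplication by the DFT
# matrix restricted to the retained frequencies; that is much cheaper
# than a full FFT at recurrence-plot sizes and identical to it on the
# retained block (the equivalence is asserted in the test suite).
.dft_cache <- new.env(parent = emptyenv())

# r x M forward DFT matrix on the retained frequencies of an M-axis.
#' @noRd
dft_restricted <- function(M, k) {
  mode_index(M, k)   # admissibility: errors when 2k - 1 > M
  key <- paste0(M, "_", k)
  if (!is.null(.dft_cache[[key]])) return(.dft_cache[[key]])
  freq <- c(seq.int(0L, k - 1L), if (k > 1L) seq.int(-(k - 1L), -1L))
  E <- exp(-2i * pi * outer(freq, seq_len(M) - 1L) / M)
  .dft_cache[[key]] <- E
  E
}

# Restricted 2-D transform of a (M, M, K) stack: Vb[a, b, k] =
# sum_{x,y} E[a,x] v[x,y,k] E[b,y], returned as (r, r, K).
#' @noRd
fwd_transform <- function(v, E) {
  M <- ncol(E); r <- nrow(E); K <- length(v) / (M * M)
  y1 <- E %*% matrix(v, M, M * K)                       # [a, (y, k)]
  a1 <- aperm(array(y1, c(r, M, K)), c(2, 1, 3))        # [y, a, k]
  y2 <- E %*% matrix(a1, M, r * K)                      # [b, (a, k)]
  aperm(array(y2, c(r, r, K)), c(2, 1, 3))              # [a, b, k]
}

# Inverse restricted transform: out[x, y, k] =
# Re(sum_{a,b} Conj(E)[x,a] S[a,b,k] Conj(E)[y,b]), as (M, M, K).
#' @noRd
inv_transform <- function(S, E) {
  M <- ncol(E); r <- nrow(E); K <- length(S) / (r * r)
  D <- Conj(t(E))                                       # M x r
  o1 <- D %*% matrix(S, r, r * K)                       # [x, (b, k)]
  a1 <- aperm(array(o1, c(M, r, K)), c(2, 1, 3))        # [b, x, k]
  o2 <- D %*% matrix(a1, r, M * K)                      # [y, (x, k)]
  Re(aperm(array(o2, c(M, M, K)), c(2, 1, 3)))          # [x, y, k]
}

#' Initialise an FNO model
#'
#' Lifting/projection and the pointwise branch use uniform fan-in scaling;
#' the complex spectral weights are uniform with scale
#' `1 / (width_in * width_out)`, following standard neural-operator
#' practice. Weights are grid-size free.
#'
#' @param cfg An [fno_config()].
#' @param seed Integer seed; initialisation is deterministic given it.
#' @return Object of class `fno_model` (fields: `cfg`, `params`, `seed`,
#'   and slots for the recurrence-plot `normalizer` and `encoding`
#'   configuration that training fills in).
#' @export
fno_init <- function(cfg = fno_config(), seed = 1L) {
  stopifnot(inherits(cfg, "fno_config"))
  r <- 2L * cfg$modes - 1L
  w <- cfg$width
  with_seed(seed, {
    params <- list()
    lift <- init_linear(cfg$input_steps, w)
    params$lift_W <- lift$W; params$lift_b <- lift$b
    sc <- 1 / (w * w)
    for (n in seq_len(cfg$num_layers)) {
      params[[paste0("spec_re_", n)]] <-
        array(stats::runif(r * r * w * w, -sc, sc), c(r, r, w, w))
      params[[paste0("spec_im_", n)]] <-
        array(stats::runif(r * r * w * w, -sc, sc), c(r, r, w, w))
      lin <- init_linear(w, w)
      params[[paste0("pw_W_", n)]] <- lin$W
      params[[paste0("pw_b_", n)]] <- lin$b
    }
    proj <- init_linear(w, cfg$horizon)
    params$proj_W <- proj$W; params$proj_b <- proj$b
    structure(list(cfg = cfg, params = params, seed = as.integer(seed),
                   normalizer = NULL, encoding = NULL),
              class = "fno_model")
  })
}

#' @export
print.fno_model <- function(x, ...) {
  cat(sprintf("<fno_model> N = %d layers, width %d, k = %d modes, T = %d -> T_hat = %d, %d parameters%s\n",
              x$cfg$num_layers, x$cfg$width, x$cfg$modes,
              x$cfg$input_steps, x$cfg$horizon, n_params(x),
              if (is.null(x$normalizer)) " (untrained)" else ""))
  invisible(x)
}

#' Spectral convolution: the Fourier module of one layer
#'
#' FFT each channel over the grid, mix the retained low-frequency block
#' across channels with the complex mode weights, zero every other mode,
#' and inverse-transform back to a real-valued state.
#'
#' @param v State array (M, M, B, C_in), real (batch dim before channels).
#' @param Wre,Wim Real and imaginary parts of the mode weights,
#'   arrays (2k-1, 2k-1, C_in, C_out).
#' @param k Retained frequencies per axis.
#' @return List with `out` (M, M, B, C_out) and `Vb` (retained-mode
#'   transform of the input, cached for the backward pass).
#' @export
fourier_module <- function(v, Wre, Wim, k) {
  d <- dim(v)
  M <- d[1]; B <- d[3]; C <- d[4]
  Cout <- dim(Wre)[4]
  E <- dft_restricted(M, k)
  cpp_spectral_forward(v, E, Wre, Wim, M, B, C, Cout)
}

#' One Fourier layer: sigmoid of spectral branch plus pointwise branch
#'
#' `v_out = sigmoid(fourier_module(v) + W v + b)`, every output entry in
#' (0, 1).
#'
#' @inheritParams fourier_module
#' @param W,b Pointwise linear branch (C_in x C_out matrix and bias).
#' @return List with `out` and the caches needed for the backward pass.
#' @export
fourier_layer <- function(v, Wre, Wim, k, W, b) {
  fm <- fourier_module(v, Wre, Wim, k)
  z <- fm$out + pw_forward(v, W, b)
  list(out = sigmoid(z), Vb = fm$Vb)
}

#' Forward pass of the FNO
#'
#' @param model An `fno_model`.
#' @param x Input frames: array (M, M, T) for one sample or (M, M, T, B)
#'   for a batch, already normalised to the model's recurrence-plot scale.
#' @return Predicted frames with matching shape, (M, M, T_hat[, B]).
#' @examples
#' m <- fno_init(fno_config(num_layers = 1, width = 4, modes = 2,
#'                          input_steps = 3, horizon = 2), seed = 1)
#' dim(fno_forward(m, array(rnorm(9 * 9 * 3), c(9, 9, 3))))  # 9 9 2
#' @export
fno_forward <- function(model, x) {
  stopifnot(inherits(model, "fno_model"))
  single <- length(dim(x)) == 3L
  # internal state layout is (M, M, B, C): a single sample needs only a
  # singleton batch axis inserted, a batch needs its last two axes swapped
  x <- if (single) array(x, c(dim(x)[1:2], 1L, dim(x)[3]))
       else aperm(x, c(1, 2, 4, 3))
  out <- forward_pass(model, x)$out
  if (single) array(out, dim(out)[c(1, 2, 4)]) else aperm(out, c(1, 2, 4, 3))
}

#' @keywords internal
#' @export
forward_pass.fno_model <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg
  d <- dim(x)
  if (d[4] != cfg$input_steps)
    stop(sprintf("input has %d frames, model expects T = %d",
                 d[4], cfg$input_steps), call. = FALSE)
  M <- d[1]; B <- d[3]; w <- cfg$width
  E <- dft_restricted(M, cfg$modes)   # errors if k inadmissible at M
  p <- model$params
  # the state lives as a (M^2 B) x channels matrix; the spectral kernels
  # read the grid/batch structure from (M, B) directly
  dim(x) <- c(M * M * B, cfg$input_steps)
  v <- sweep(x %*% p$lift_W, 2L, p$lift_b, "+")
  cache <- if (keep_cache) list(x = x, M = M, B = B,
                                layers = vector("list", cfg$num_layers))
  for (n in seq_len(cfg$num_layers)) {
    fm <- cpp_spectral_forward(v, E, p[[paste0("spec_re_", n)]],
                               p[[paste0("spec_im_", n)]], M, B, w, w)
    z <- fm$out
    dim(z) <- dim(v)
    out <- sigmoid(z + sweep(v %*% p[[paste0("pw_W_", n)]], 2L,
                             p[[paste0("pw_b_", n)]], "+"))
    if (keep_cache) cache$layers[[n]] <- list(v_in = v, Vb = fm$Vb,
                                              out = out)
    v <- out
  }
  out <- sweep(v %*% p$proj_W, 2L, p$proj_b, "+")
  dim(out) <- c(M, M, B, cfg$horizon)
  if (keep_cache) cache$vN <- v
  list(out = out, cache = cache)
}

#' @keywords internal
#' @export
backward_pass.fno_model <- function(model, cache, dout) {
  cfg <- model$cfg
  p <- model$params
  M <- cache$M; B <- cache$B; w <- cfg$width
  E <- dft_restricted(M, cfg$modes)
  grads <- list()
  dim(dout) <- c(M * M * B, cfg$horizon)
  grads$proj_W <- crossprod(cache$vN, dout)
  grads$proj_b <- colSums(dout)
  dv <- dout %*% t(p$proj_W)
  for (n in rev(seq_len(cfg$num_layers))) {
    ly <- cache$layers[[n]]
    dz <- dv * ly$out * (1 - ly$out)           # sigmoid derivative
    sb <- cpp_spectral_backward(dz, ly$Vb, E, p[[paste0("spec_re_", n)]],
                                p[[paste0("spec_im_", n)]], M, B, w, w)
    grads[[paste0("spec_re_", n)]] <- sb$dWre
    grads[[paste0("spec_im_", n)]] <- sb$dWim
    grads[[paste0("pw_W_", n)]] <- crossprod(ly$v_in, dz)
    grads[[paste0("pw_b_", n)]] <- colSums(dz)
    dvs <- sb$dv
    dim(dvs) <- dim(dz)
    dv <- dvs + dz %*% t(p[[paste0("pw_W_", n)]])
  }
  grads$lift_W <- crossprod(cache$x, dv)
  grads$lift_b <- colSums(dv)
  grads
}

#' Evaluate a trained FNO at a different grid resolution
#'
#' Runs the same spectral weights on frames of a new grid size M' (FFT at
#' M', identical retained modes) with no retraining — the operator's mesh
#' invariance. M' must admit the model's mode count
#' (`2 * modes - 1 <= M'`).
#'
#' @param model A trained `fno_model`.
#' @param frames Input frames (M', M', T) or (M', M', T, B), normalised to
#'   the model's recurrence-plot scale.
#' @return Predicted frames at grid size M'.
#' @export
evaluate_at_resolution <- function(model, frames) {
  mode_index(dim(frames)[1], model$cfg$modes)
  fno_forward(model, frames)
}

#' Resolution-transfer error of a trained forecaster
#'
#' Quantifies mesh invariance: the stream is re-encoded at smaller window
#' sizes Tw' (grid sizes M' = 6 Tw' - 1), the fixed trained weights are
#' run on the new grids, and each prediction is compared with the
#' native-resolution prediction for the same underlying window, resized to
#' M' with [resize_frames()]. Reported as relative Frobenius error
#' ||resized_native - direct||_F / ||direct||_F pooled over samples and
#' frames.
#'
#' @param model An `fno_model` trained at the encoding in
#'   `model$encoding` (window size 5, grid 29 under defaults).
#' @param stream The [sensor_stream()] to evaluate on.
#' @param sample_idx Sample indices (in the native encoding) to compare.
#' @param window_sizes Window sizes Tw' to transfer to (default 4 and 3,
#'   i.e. grids 23 and 17).
#' @param chunk Samples per forward pass.
#' @return Named numeric vector of relative Frobenius errors, one per
#'   grid size.
#' @export
resolution_transfer_error <- function(model, stream, sample_idx,
                                      window_sizes = c(4L, 3L),
                                      chunk = 64L) {
  stopifnot(inherits(model, "fno_model"), !is.null(model$normalizer))
  cfg <- model$encoding
  ds0 <- encode_dataset(stream, cfg)
  sc <- model$normalizer$scale
  out <- numeric(0)
  for (twp in window_sizes) {
    cfgp <- encoding_config(window_size = twp, stride = cfg$stride,
                            interpolate = cfg$interpolate,
                            input_steps = cfg$input_steps,
                            horizon = cfg$horizon)
    dsp <- encode_dataset(stream, cfgp)
    # window ending at sample t has index t - Tw + 1: shift aligns anchors
    shift <- cfg$window_size - twp
    idxp <- sample_idx + shift
    stopifnot(all(idxp >= 1), all(idxp <= dsp$n_samples))
    Mp <- dsp$M
    num <- 0; den <- 0
    for (part in split(seq_along(sample_idx),
                       ceiling(seq_along(sample_idx) / chunk))) {
      g0 <- gather_batch(ds0, sample_idx[part], sc)
      gp <- gather_batch(dsp, idxp[part], sc)
      pred0 <- forward_pass(model, g0$x)$out      # (M, M, B, H)
      predp <- forward_pass(model, gp$x)$out      # (Mp, Mp, B, H)
      d0 <- dim(pred0)
      res <- resize_frames(array(pred0, c(d0[1], d0[2], d0[3] * d0[4])), Mp)
      num <- num + sum((as.vector(res) - as.vector(predp))^2)
      den <- den + sum(predp^2)
    }
    out[paste0("M", Mp)] <- sqrt(num / den)
  }
  out
}

#' Bilinear resize of recurrence-plot frames to a new grid size
#'
#' Used to compare predictions made at different resolutions: separable
#' linear interpolation `P A t(P)` with sampling positions spread evenly
#' over the source grid.
#'
#' @param frames Matrix (M x M) or array (M, M, K).
#' @param M_new Target side length.
#' @return Resized matrix or array.
#' @export
resize_frames <- function(frames, M_new) {
  single <- is.matrix(frames)
  if (single) frames <- array(frames, c(dim(frames), 1L))
  M <- dim(frames)[1]
  pos <- seq(1, M, length.out = M_new)
  lo <- pmin(floor(pos), M - 1L)
  whi <- pos - lo
  P <- matrix(0, M_new, M)
  P[cbind(seq_len(M_new), lo)] <- 1 - whi
  P[cbind(seq_len(M_new), lo + 1L)] <- P[cbind(seq_len(M_new), lo + 1L)] + whi
  out <- array(0, c(M_new, M_new, dim(frames)[3]))
  for (k in seq_len(dim(frames)[3]))
    out[, , k] <- P %*% frames[, , k] %*% t(P)
  if (single) out[, , 1] else out
}
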