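# Shared neural-network machinery: batched 2-D FFTs, parameter
# initialisation, the Adam optimiser, and the forward/backward generics the
# training loop dispatches on.
#
# There is deliberately no external deep-learning dependency: the models in
# this package are small and fully specified, and owning the forward and
# backward passes keeps training bit-reproducible under a fixed seed and
# lets the test suite verify every gradient against finite differences.

#' Batched 2-D discrete Fourier transform
#'
#' Transforms each M1 x M2 slice of a (M1, M2, K) array, using two batched
#' calls to [stats::mvfft()]. Unnormalised in both directions (like the
#' underlying FFT); callers divide by `M1 * M2` where a normalised inverse
#' is required.
#'
#' @param x Real or complex array with dim (M1, M2, K).
#' @param inverse Use the inverse (conjugate) transform.
#' @return Complex array of the same dim.
#' @keywords internal
fft2_stack <- function(x, inverse = FALSE) {
  d <- dim(x)
  a <- stats::mvfft(matrix(x, d[1], d[2] * d[3]), inverse = inverse)
  a <- aperm(array(a, d), c(2, 1, 3))
  a <- stats::mvfft(matrix(a, d[2], d[1] * d[3]), inverse = inverse)
  aperm(array(a, c(d[2], d[1], d[3])), c(2, 1, 3))
}

# Uniform fan-in initialisation for a dense map.
#' @noRd
init_linear <- function(fan_in, fan_out) {
  s <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out),
       b = numeric(fan_out))
}

# Pointwise (per-grid-point) linear map on a state stored channel-last,
# (M, M, B, C): a plain reshape exposes the channels as matrix columns.
#' @noRd
pw_forward <- function(v, W, b) {
  d <- dim(v)
  y <- matrix(v, ncol = d[4]) %*% W
  y <- sweep(y, 2L, b, "+")
  array(y, c(d[1], d[2], d[3], ncol(W)))
}

# Backward of pw_forward: returns grads and upstream gradient.
#' @noRd
pw_backward <- function(v, W, dy) {
  d <- dim(v)
  x <- matrix(v, ncol = d[4])
  dym <- matrix(dy, ncol = ncol(W))
  list(dW = crossprod(x, dym),
       db = colSums(dym),
       dv = array(dym %*% t(W), d))
}

#' Initialise Adam optimiser state
#' @param params Named list of numeric arrays.
#' @keywords internal
adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' One Adam update step
#'
#' @param params,grads Named lists of conformable numeric arrays.
#' @param state State from [adam_init()].
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @return List with updated `params` and `state`.
#' @keywords internal
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (!identical(dim(g), dim(params[[nm]]))) dim(g) <- dim(params[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Forward pass of a forecasting model (internal generic)
#'
#' @param model A model object (`fno_model` or `cnn_model`).
#' @param x Input batch, array (M, M, T, B).
#' @param keep_cache Retain intermediate states for [backward_pass()].
#' @return List with `out` (M, M, T_hat, B) and, if requested, `cache`.
#' @keywords internal
forward_pass <- function(model, x, keep_cache = FALSE) UseMethod("forward_pass")

#' Backward pass: gradients of the scalar loss w.r.t. all parameters
#'
#' @param model Model object.
#' @param cache Cache from [forward_pass()].
#' @param dout Gradient of the loss w.r.t. the output stack.
#' @return Named list of gradients matching `model$params`.
#' @keywords internal
backward_pass <- function(model, cache, dout) UseMethod("backward_pass")

#' Number of trainable parameters of a model
#' @param model A model object.
#' @return Integer parameter count (complex spectral weights count their
#'   real and imaginary parts separately).
#' @export
n_params <- function(model) UseMethod("n_params")

#' @export
n_params.default <- function(model) sum(vapply(model$params, length, 1L))
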