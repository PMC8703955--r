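# Recurrence-plot encoding: sliding concatenated windows over the three
# axes, midpoint interpolation, distance-only recurrence / cross-recurrence
# plots, and assembly into supervised forecasting samples.

#' Encoding configuration
#'
#' @param window_size Samples per axis entering one window (Tw, default 5).
#' @param stride Step between consecutive windows in samples (default 1).
#' @param interpolate Insert one midpoint between consecutive entries of the
#'   concatenated window vector (default `TRUE`), growing length L to 2L-1.
#' @param input_steps Number of input frames per forecasting sample
#'   (T, default 30: 1 s of frames at 30 Hz with stride 1).
#' @param horizon Number of forecast frames (T-hat, default 20: about 0.6 s).
#' @return Object of class `encoding_config`.
#' @export
encoding_config <- function(window_size = 5L, stride = 1L, interpolate = TRUE,
                            input_steps = 30L, horizon = 20L) {
  stopifnot(window_size >= 1, stride >= 1, input_steps >= 1, horizon >= 1)
  structure(list(window_size = as.integer(window_size),
                 stride = as.integer(stride),
                 interpolate = isTRUE(interpolate),
                 input_steps = as.integer(input_steps),
                 horizon = as.integer(horizon)),
            class = "encoding_config")
}

#' Grid side length implied by an encoding configuration
#'
#' With interpolation the concatenated 3*Tw vector grows to
#' `M = 2 * (3 * Tw) - 1` (29 for Tw = 5); without it M = 3*Tw.
#' @param cfg An [encoding_config()].
#' @export
grid_size <- function(cfg) {
  m <- 3L * cfg$window_size
  if (cfg$interpolate) 2L * m - 1L else m
}

#' Slide concatenated windows over a stream's three axes
#'
#' For each end index t (from Tw to N in steps of the stride) emits the
#' concatenation of the Tw most recent samples of each axis ending at t:
#' `[x_{t-Tw+1..t}; y_{t-Tw+1..t}; z_{t-Tw+1..t}]`, a vector of length 3*Tw.
#'
#' @param stream A [sensor_stream()].
#' @param cfg An [encoding_config()].
#' @return A `window_set`: list with `values` (3Tw x n matrix, one window
#'   per column), `t_index` (1-based end sample of each window), and
#'   `interpolated = FALSE`.
#' @export
window_axes <- function(stream, cfg = encoding_config()) {
  stopifnot(inherits(stream, "sensor_stream"), inherits(cfg, "encoding_config"))
  n <- ncol(stream$axes)
  tw <- cfg$window_size
  if (n < tw)
    stop(sprintf("stream has %d samples, need at least window_size = %d", n, tw),
         call. = FALSE)
  ends <- seq.int(tw, n, by = cfg$stride)
  idx <- outer(seq.int(-(tw - 1L), 0L), ends, "+")  # Tw x n sample indices
  values <- rbind(matrix(stream$axes[1, ][idx], nrow = tw),
                  matrix(stream$axes[2, ][idx], nrow = tw),
                  matrix(stream$axes[3, ][idx], nrow = tw))
  structure(list(values = values, t_index = ends, interpolated = FALSE),
            class = "window_set")
}

#' Midpoint-interpolate a window vector
#'
#' Inserts the arithmetic midpoint between each consecutive pair of the
#' concatenated vector (treated as one sequence, crossing axis boundaries),
#' so length L becomes 2L - 1 and the original entries sit at odd (1-based)
#' positions. Also accepts a matrix (columns are windows) or a `window_set`.
#'
#' @param w Numeric vector of length >= 2, a matrix, or a `window_set`.
#' @return Same shape of object with interpolated values.
#' @examples
#' interpolate_window(c(0, 2))      # 0 1 2
#' interpolate_window(c(1, 4, 9))   # 1 2.5 4 6.5 9
#' @export
interpolate_window <- function(w) {
  if (inherits(w, "window_set")) {
    if (w$interpolated) return(w)
    w$values <- interpolate_window(w$values)
    w$interpolated <- TRUE
    return(w)
  }
  x <- if (is.matrix(w)) w else matrix(w, ncol = 1L)
  L <- nrow(x)
  if (L < 2L) stop("need at least 2 entries to interpolate", call. = FALSE)
  out <- matrix(0, 2L * L - 1L, ncol(x))
  out[seq.int(1L, 2L * L - 1L, by = 2L), ] <- x
  out[seq.int(2L, 2L * L - 2L, by = 2L), ] <-
    (x[-L, , drop = FALSE] + x[-1L, , drop = FALSE]) / 2
  if (is.matrix(w)) out else out[, 1L]
}

#' Distance-only recurrence plot of a window vector
#'
#' `Y[i, j] = |x_i - x_j|`: the pairwise distance image of the (scalar)
#' entries of one concatenated window, with no threshold and no step
#' function, so no information is lost to binarisation. The result is
#' symmetric, has a zero diagonal, and satisfies the triangle bound
#' `|Y[i,k] - Y[k,j]| <= Y[i,j]`.
#'
#' @param x Numeric window vector (typically the interpolated 29-vector).
#' @return M x M nonnegative matrix.
#' @export
recurrence_plot <- function(x) {
  if (length(x) < 1L) stop("empty window vector", call. = FALSE)
  abs(outer(x, x, "-"))
}

#' Cross recurrence plot of two window vectors
#'
#' `Y[i, j] = |x_i - y_j|` compares the states of two sensors (e.g.
#' gyroscope rows against accelerometer columns) observed over the same
#' window. Not symmetric in general; the diagonal need not be zero.
#'
#' @param x,y Numeric window vectors of equal (post-interpolation) length.
#' @return M x M nonnegative matrix.
#' @export
cross_recurrence_plot <- function(x, y) {
  if (length(x) != length(y))
    stop(sprintf("window lengths differ: %d vs %d", length(x), length(y)),
         call. = FALSE)
  abs(outer(x, y, "-"))
}

# Vectorised frame builder: columns of X (and Y for CRP) are window vectors.
# Returns an M x M x n array with frame w = |X[i,w] - Y[j,w]|.
#' @noRd
build_frames <- function(X, Y = X) {
  M <- nrow(X)
  ii <- rep(seq_len(M), times = M)
  jj <- rep(seq_len(M), each = M)
  array(abs(X[ii, , drop = FALSE] - Y[jj, , drop = FALSE]),
        dim = c(M, M, ncol(X)))
}

#' Encode a stream as a sequence of recurrence-plot frames
#'
#' Runs the full encoding: sliding concatenated windows, optional midpoint
#' interpolation, and one distance-only recurrence plot per window. If
#' `accel` is supplied, frames are cross recurrence plots pairing the
#' (interpolated) gyroscope window with the accelerometer window ending at
#' the same sample index.
#'
#' @param stream A gyroscope [sensor_stream()].
#' @param cfg An [encoding_config()].
#' @param accel Optional accelerometer [sensor_stream()] of the same length
#'   and rate for cross-recurrence fusion.
#' @return An `rp_frames` object: `frames` (M x M x n array), `t_index`,
#'   `M`, `cfg`.
#' @export
encode_stream <- function(stream, cfg = encoding_config(), accel = NULL) {
  ws <- window_axes(stream, cfg)
  if (cfg$interpolate) ws <- interpolate_window(ws)
  if (is.null(accel)) {
    frames <- build_frames(ws$values)
  } else {
    stopifnot(inherits(accel, "sensor_stream"))
    if (ncol(accel$axes) != ncol(stream$axes))
      stop("gyroscope and accelerometer streams differ in length", call. = FALSE)
    wa <- window_axes(accel, cfg)
    if (cfg$interpolate) wa <- interpolate_window(wa)
    frames <- build_frames(ws$values, wa$values)
  }
  structure(list(frames = frames, t_index = ws$t_index,
                 M = dim(frames)[1], cfg = cfg),
            class = "rp_frames")
}

#' Assemble supervised forecasting samples from encoded frames
#'
#' A sample pairs T consecutive input frames with the next T-hat target
#' frames and the raw 3-axis signal samples aligned to the target frames'
#' end indices. Samples are indexed lazily: the dataset stores the frame
#' array once and materialises a sample on request via [get_sample()].
#'
#' @param frames An `rp_frames` object from [encode_stream()].
#' @param stream The [sensor_stream()] the frames were encoded from (source
#'   of the aligned raw target signals).
#' @param cfg The [encoding_config()] (for T and T-hat).
#' @param subject_id,motion Optional labels carried with the dataset.
#' @return An `rp_dataset` with `n_samples = n_frames - T - T_hat + 1`.
#' @export
assemble_samples <- function(frames, stream, cfg = frames$cfg,
                             subject_id = NA_character_,
                             motion = NA_character_) {
  stopifnot(inherits(frames, "rp_frames"), inherits(stream, "sensor_stream"))
  nf <- dim(frames$frames)[3]
  need <- cfg$input_steps + cfg$horizon
  if (nf < need)
    stop(sprintf("need at least T + T_hat = %d frames, have %d", need, nf),
         call. = FALSE)
  n <- nf - need + 1L
  structure(list(frames = frames$frames, t_index = frames$t_index,
                 signals = stream$axes, rate_hz = stream$rate_hz,
                 M = frames$M, cfg = cfg,
                 n_samples = n, starts = seq_len(n),
                 sample_motion = rep(motion, n),
                 subject_id = subject_id, motion = motion),
            class = "rp_dataset")
}

#' One-call encoder: stream to forecasting dataset
#'
#' @inheritParams encode_stream
#' @inheritParams assemble_samples
#' @return An `rp_dataset`.
#' @export
encode_dataset <- function(stream, cfg = encoding_config(), accel = NULL,
                           subject_id = NA_character_, motion = NA_character_) {
  assemble_samples(encode_stream(stream, cfg, accel), stream, cfg,
                   subject_id, motion)
}

#' @export
print.rp_dataset <- function(x, ...) {
  cat(sprintf("<rp_dataset> %s/%s: %d frames of %dx%d, %d samples (T=%d, T_hat=%d)\n",
              x$subject_id, x$motion, dim(x$frames)[3], x$M, x$M,
              x$n_samples, x$cfg$input_steps, x$cfg$horizon))
  invisible(x)
}

#' Number of forecasting samples in a dataset
#' @param ds An `rp_dataset`.
#' @export
n_samples <- function(ds) ds$n_samples

#' Materialise one forecasting sample
#'
#' @param ds An `rp_dataset`.
#' @param i Sample index in `1..n_samples(ds)`.
#' @return List with `input_frames` (M x M x T), `target_frames`
#'   (M x M x T_hat), `target_signal` (3 x T_hat raw samples at the target
#'   frames' end indices), and `t_index` of the target frames.
#' @export
get_sample <- function(ds, i) {
  stopifnot(inherits(ds, "rp_dataset"))
  if (i < 1L || i > ds$n_samples) stop("sample index out of range", call. = FALSE)
  s <- ds$starts[i]
  T <- ds$cfg$input_steps; H <- ds$cfg$horizon
  tgt <- (s + T):(s + T + H - 1L)
  list(input_frames = ds$frames[, , s:(s + T - 1L), drop = FALSE],
       target_frames = ds$frames[, , tgt, drop = FALSE],
       target_signal = ds$signals[, ds$t_index[tgt], drop = FALSE],
       t_index = ds$t_index[tgt])
}

#' Contiguous sub-dataset of a forecasting dataset
#'
#' Keeps samples `first..last` (and exactly the frames they span), e.g. to
#' carve the chronological training portion out of one recording before
#' pooling recordings with [concat_datasets()].
#'
#' @param ds An `rp_dataset`.
#' @param first,last Sample index range to keep.
#' @return An `rp_dataset` with `last - first + 1` samples.
#' @export
subset_dataset <- function(ds, first, last) {
  stopifnot(inherits(ds, "rp_dataset"),
            first >= 1, last <= ds$n_samples, first <= last)
  span <- ds$cfg$input_steps + ds$cfg$horizon
  fidx <- ds$starts[first]:(ds$starts[last] + span - 1L)
  out <- ds
  out$frames <- ds$frames[, , fidx, drop = FALSE]
  out$t_index <- ds$t_index[fidx]
  out$n_samples <- last - first + 1L
  out$starts <- seq_len(out$n_samples)
  out$sample_motion <- ds$sample_motion[first:last]
  out
}

#' Pool several forecasting datasets into one
#'
#' Concatenates the frame sequences of compatible datasets (same grid size
#' and encoding) so one model can train on all of them; no sample ever
#' spans two source recordings.
#'
#' @param ds_list List of `rp_dataset`s.
#' @return An `rp_dataset` whose samples are the union of the inputs'.
#' @export
concat_datasets <- function(ds_list) {
  stopifnot(length(ds_list) >= 1)
  if (length(ds_list) == 1L) return(ds_list[[1]])
  M <- ds_list[[1]]$M
  cfg <- ds_list[[1]]$cfg
  for (d in ds_list)
    if (d$M != M || !identical(unclass(d$cfg), unclass(cfg)))
      stop("datasets have incompatible grid sizes or encodings", call. = FALSE)
  frame_off <- 0L; sig_off <- 0L
  frames <- vector("list", length(ds_list)); starts <- integer(0)
  t_index <- integer(0); motion <- character(0)
  for (j in seq_along(ds_list)) {
    d <- ds_list[[j]]
    frames[[j]] <- d$frames
    starts <- c(starts, d$starts + frame_off)
    t_index <- c(t_index, d$t_index + sig_off)
    motion <- c(motion, d$sample_motion)
    frame_off <- frame_off + dim(d$frames)[3]
    sig_off <- sig_off + ncol(d$signals)
  }
  all_frames <- array(unlist(frames), c(M, M, frame_off))
  out <- ds_list[[1]]
  out$frames <- all_frames
  out$t_index <- t_index
  out$signals <- do.call(cbind, lapply(ds_list, `[[`, "signals"))
  out$n_samples <- length(starts)
  out$starts <- starts
  out$sample_motion <- motion
  out$motion <- paste(unique(motion), collapse = "+")
  out
}

#' Fit the recurrence-plot normalizer on training frames
#'
#' Frames are divided by the training split's global maximum before they
#' enter any model, keeping the sigmoid-activated spectral layers in a
#' consistent input range. The normalizer is stored with every trained
#' model so inference at any later time (or resolution) reuses it.
#'
#' @param ds An `rp_dataset`.
#' @param sample_idx Training sample indices (frames spanned by these
#'   samples define the maximum); defaults to all samples.
#' @return List with element `scale` (positive scalar).
#' @export
fit_rp_normalizer <- function(ds, sample_idx = seq_len(ds$n_samples)) {
  stopifnot(inherits(ds, "rp_dataset"))
  span <- ds$cfg$input_steps + ds$cfg$horizon
  fidx <- unique(as.vector(outer(ds$starts[sample_idx],
                                 seq.int(0L, span - 1L), "+")))
  sc <- max(ds$frames[, , fidx])
  if (sc <= 0) sc <- 1
  list(scale = sc)
}
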