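# Sensor stream container and IO: reading timestamped CSV recordings,
# trimming start/stop guard intervals, and resampling onto a uniform grid.

#' Construct a sensor stream
#'
#' A sensor stream is a fixed-rate, timestamped, 3-axis angular-velocity
#' (gyroscope, rad/s) or acceleration (accelerometer, m/s^2) sequence.
#'
#' @param timestamps Strictly increasing numeric vector of times (seconds).
#' @param axes 3 x N numeric matrix, rows x/y/z.
#' @param rate_hz Nominal sampling rate (Hz).
#' @param sensor_kind `"gyroscope"` or `"accelerometer"`.
#' @return Object of class `sensor_stream`.
#' @export
sensor_stream <- function(timestamps, axes,
                          rate_hz = 1 / stats::median(diff(timestamps)),
                          sensor_kind = c("gyroscope", "accelerometer")) {
  sensor_kind <- match.arg(sensor_kind)
  axes <- as.matrix(axes)
  if (nrow(axes) != 3L) stop("axes must be a 3 x N matrix", call. = FALSE)
  if (ncol(axes) != length(timestamps))
    stop("timestamps and axes disagree in length", call. = FALSE)
  if (length(timestamps) < 1L) stop("stream is empty", call. = FALSE)
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  rownames(axes) <- c("x", "y", "z")
  structure(list(timestamps = as.numeric(timestamps), axes = axes,
                 rate_hz = rate_hz, sensor_kind = sensor_kind),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s, %d samples @ %.2f Hz (%.1f s)\n",
              x$sensor_kind, ncol(x$axes), x$rate_hz,
              ncol(x$axes) / x$rate_hz))
  invisible(x)
}

#' Stream duration in seconds
#'
#' Defined as N / rate: the span of the half-open interval covered by the
#' samples, including the trailing inter-sample gap, so a 60 s recording at
#' 30 Hz has duration 60 exactly.
#' @param stream A `sensor_stream`.
#' @export
stream_duration <- function(stream) ncol(stream$axes) / stream$rate_hz

#' Write a stream as CSV
#'
#' Columns `t_s,x,y,z` with a header row, one row per sample.
#' @param stream A `sensor_stream`.
#' @param path Output path.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  df <- data.frame(t_s = stream$timestamps,
                   x = stream$axes[1, ], y = stream$axes[2, ],
                   z = stream$axes[3, ])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stream from CSV
#'
#' Expects columns `t_s,x,y,z` (header row). The rate is inferred from the
#' median timestamp spacing. Missing columns, non-monotone timestamps and
#' empty files are rejected with file context.
#'
#' @param path CSV file path.
#' @param sensor_kind `"gyroscope"` or `"accelerometer"`.
#' @return A [sensor_stream()].
#' @export
read_stream <- function(path, sensor_kind = c("gyroscope", "accelerometer")) {
  sensor_kind <- match.arg(sensor_kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("t_s", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  if (nrow(df) == 0L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  if (nrow(df) > 1L && any(diff(df$t_s) <= 0)) {
    i <- which(diff(df$t_s) <= 0)[1]
    stop(sprintf("%s: timestamps not strictly increasing at data row %d",
                 path, i + 1L), call. = FALSE)
  }
  rate <- if (nrow(df) > 1L) 1 / stats::median(diff(df$t_s)) else NA_real_
  sensor_stream(df$t_s, t(as.matrix(df[, c("x", "y", "z")])), rate, sensor_kind)
}

#' Trim start/stop guard intervals
#'
#' Removes `round(head_s * rate)` leading and `round(tail_s * rate)` trailing
#' samples — the seconds around pressing start/stop that do not contain the
#' predefined motion. Timestamps are re-zeroed so sample i sits at
#' `(i - 1) / rate` after the trim.
#'
#' @param stream A [sensor_stream()].
#' @param head_s,tail_s Seconds to remove at each end (default 3 each).
#' @return The trimmed [sensor_stream()].
#' @export
trim_guard <- function(stream, head_s = 3, tail_s = 3) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (head_s < 0 || tail_s < 0) stop("trim lengths must be >= 0", call. = FALSE)
  n <- ncol(stream$axes)
  nh <- round(head_s * stream$rate_hz)
  nt <- round(tail_s * stream$rate_hz)
  if (nh + nt >= n)
    stop(sprintf("trim of %d + %d samples exceeds stream length %d",
                 nh, nt, n), call. = FALSE)
  keep <- (nh + 1L):(n - nt)
  ts <- stream$timestamps[keep]
  sensor_stream(ts - ts[1], stream$axes[, keep, drop = FALSE],
                stream$rate_hz, stream$sensor_kind)
}

#' Resample a stream onto a uniform grid
#'
#' Per-axis linear interpolation onto a uniform grid at `target_hz`. The
#' grid is half-open over the stream's duration (N_src / rate_src seconds):
#' `count = floor(duration * target_hz)`, so 60 s at 30 Hz stays exactly
#' 1800 samples and resampling a uniform stream to its own rate is the
#' identity.
#'
#' @param stream A [sensor_stream()].
#' @param target_hz Target rate (Hz).
#' @return A [sensor_stream()] at `target_hz`.
#' @export
resample_stream <- function(stream, target_hz) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (target_hz <= 0) stop("target_hz must be > 0", call. = FALSE)
  n <- ncol(stream$axes)
  if (n < 2L) stop("cannot resample a single-sample stream", call. = FALSE)
  duration <- stream_duration(stream)
  n_out <- floor(duration * target_hz + 1e-9)
  t0 <- stream$timestamps[1]
  grid <- t0 + (seq_len(n_out) - 1) / target_hz
  axes <- matrix(0, 3, n_out, dimnames = list(c("x", "y", "z"), NULL))
  for (a in 1:3)
    axes[a, ] <- stats::approx(stream$timestamps, stream$axes[a, ],
                               xout = grid, rule = 2)$y
  sensor_stream(grid, axes, target_hz, stream$sensor_kind)
}
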