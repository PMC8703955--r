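# Synthetic quasi-periodic motion generator.
#
# Emulates thigh-worn gyroscope (and accelerometer) recordings of walking and
# running as per-axis harmonic sums with subject-specific stride frequency,
# amplitudes and phases, plus Gaussian sensor noise, and injects burst-then-
# rest fall transients.  Every downstream stage (encoding, forecasting,
# decoding, fall alerting) is exercised on these streams.

WALK_FREQ_RANGE <- c(1.4, 2.0)   # Hz, stride frequency while walking
RUN_FREQ_RANGE  <- c(2.4, 3.0)   # Hz, while running
AMP_RANGE       <- c(0.5, 3.0)   # rad/s, base harmonic amplitude
GRAVITY_MS2     <- 9.81          # constant offset on the accelerometer z axis

#' Create a synthetic subject profile
#'
#' A subject profile fixes the gait model of one simulated wearer: a
#' fundamental stride frequency (drawn from 1.4--2.0 Hz for walking,
#' 2.4--3.0 Hz for running), 2--3 harmonics per axis with axis-specific
#' amplitudes (rad/s, decaying with harmonic order) and phases, and a sensor
#' noise level. Profiles are deterministic given `seed`, and different seeds
#' give different frequencies/amplitudes, which is what makes per-subject
#' (personalized) models distinguishable downstream.
#'
#' @param subject_id Character label for the subject.
#' @param motion_kind `"walking"` or `"running"`.
#' @param seed Integer seed controlling every random draw in the profile.
#' @param noise_sd Gaussian sensor-noise standard deviation in rad/s.
#' @return An object of class `subject_profile`.
#' @examples
#' p <- make_subject_profile("s1", "walking", seed = 7)
#' p$fundamental_freq
#' @export
make_subject_profile <- function(subject_id, motion_kind = c("walking", "running"),
                                 seed, noise_sd = 0.05) {
  if (length(motion_kind) == 1L && !motion_kind %in% c("walking", "running"))
    stop(sprintf("unknown motion_kind '%s'; must be 'walking' or 'running'",
                 motion_kind), call. = FALSE)
  motion_kind <- match.arg(motion_kind)
  stop_if_not_scalar_number(seed, "seed")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  rng <- if (motion_kind == "walking") WALK_FREQ_RANGE else RUN_FREQ_RANGE
  with_seed(seed, {
    f0 <- stats::runif(1, rng[1], rng[2])
    axes <- lapply(1:3, function(a) {
      nh <- sample(2:3, 1)
      list(
        amplitudes = stats::runif(nh, AMP_RANGE[1], AMP_RANGE[2]) / seq_len(nh),
        phases     = stats::runif(nh, 0, 2 * pi)
      )
    })
    structure(
      list(subject_id = as.character(subject_id), motion_kind = motion_kind,
           fundamental_freq = f0,
           harmonic_amplitudes = lapply(axes, `[[`, "amplitudes"),
           harmonic_phases = lapply(axes, `[[`, "phases"),
           noise_sd = noise_sd, seed = as.integer(seed)),
      class = "subject_profile")
  })
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s, %s, f0 = %.3f Hz, noise_sd = %.3g rad/s\n",
              x$subject_id, x$motion_kind, x$fundamental_freq, x$noise_sd))
  invisible(x)
}

#' Create a cohort of subject profiles with separated stride frequencies
#'
#' Draws `n` profiles and enforces a minimum pairwise gap between their
#' fundamental frequencies (redrawing colliding profiles with fresh seeds),
#' so that cross-subject evaluation has genuinely distinct subjects.
#'
#' @param n Number of subjects.
#' @param motion_kind `"walking"` or `"running"`.
#' @param seed Base integer seed; subject i uses a seed derived from it.
#' @param min_gap_hz Minimum pairwise fundamental-frequency gap (Hz).
#' @param noise_sd Per-subject sensor noise (rad/s).
#' @return List of `subject_profile` objects named by subject id.
#' @export
make_subject_cohort <- function(n, motion_kind = c("walking", "running"),
                                seed, min_gap_hz = 0.05, noise_sd = 0.05) {
  motion_kind <- match.arg(motion_kind)
  seeds <- as.integer(seed) + seq_len(n)
  profiles <- lapply(seq_len(n), function(i)
    make_subject_profile(sprintf("s%d", i), motion_kind, seeds[i], noise_sd))
  repeat {
    f <- vapply(profiles, `[[`, numeric(1), "fundamental_freq")
    d <- abs(outer(f, f, "-")); diag(d) <- Inf
    bad <- which(apply(d, 1, min) < min_gap_hz)
    if (length(bad) == 0L) break
    # redraw the later member of each colliding pair with a shifted seed
    i <- max(bad)
    seeds[i] <- seeds[i] + as.integer(n) + 1000L
    profiles[[i]] <- make_subject_profile(sprintf("s%d", i), motion_kind,
                                          seeds[i], noise_sd)
  }
  names(profiles) <- vapply(profiles, `[[`, character(1), "subject_id")
  profiles
}

#' Generate a synthetic fixed-rate sensor stream for one subject
#'
#' Each axis is a harmonic sum `sum_h A_h sin(2 pi h f0 t + phi_h)` plus
#' i.i.d. Gaussian noise. Accelerometer streams reuse the same harmonic
#' model (amplitudes read as m/s^2) with shifted phases and a gravity-like
#' constant offset on the z axis. The sample count is
#' `round(duration_s * rate_hz)` and timestamps are uniform at `1/rate_hz`.
#'
#' @param profile A `subject_profile`.
#' @param duration_s Stream duration in seconds.
#' @param rate_hz Sampling rate in Hz (the pipeline default is 30 Hz).
#' @param sensor_kind `"gyroscope"` or `"accelerometer"`.
#' @param realization Integer tag distinguishing repeated recordings of the
#'   same subject: the deterministic harmonic waveform is identical across
#'   realizations, the noise draw differs (recording the motion twice).
#' @return A [sensor_stream()] object.
#' @examples
#' p <- make_subject_profile("s1", "walking", seed = 7)
#' s <- generate_motion_stream(p, duration_s = 60, rate_hz = 30)
#' ncol(s$axes)  # 1800
#' @export
generate_motion_stream <- function(profile, duration_s = 60, rate_hz = 30,
                                   sensor_kind = c("gyroscope", "accelerometer"),
                                   realization = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  sensor_kind <- match.arg(sensor_kind)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  phase_shift <- if (sensor_kind == "accelerometer") pi / 4 else 0
  axes <- matrix(0, nrow = 3, ncol = n,
                 dimnames = list(c("x", "y", "z"), NULL))
  for (a in 1:3) {
    amps <- profile$harmonic_amplitudes[[a]]
    phis <- profile$harmonic_phases[[a]] + phase_shift
    for (h in seq_along(amps))
      axes[a, ] <- axes[a, ] +
        amps[h] * sin(2 * pi * h * profile$fundamental_freq * t + phis[h])
  }
  if (sensor_kind == "accelerometer") axes[3, ] <- axes[3, ] + GRAVITY_MS2
  if (profile$noise_sd > 0) {
    noise_seed <- profile$seed + 500000L +
      (sensor_kind == "accelerometer") * 250000L +
      1000L * (as.integer(realization) - 1L)
    axes <- axes + with_seed(noise_seed,
      matrix(stats::rnorm(3L * n, sd = profile$noise_sd), nrow = 3))
  }
  sensor_stream(t, axes, rate_hz, sensor_kind)
}

#' Inject a fall transient into a stream
#'
#' From `onset_s` the stream is overwritten with a high-amplitude broadband
#' burst (impact; peak amplitude `burst_gain` times the pre-onset per-axis
#' absolute maximum, duration `burst_s`) followed by near-zero signal
#' (post-impact rest) until the end of the stream. The per-sample label
#' track marks burst and rest as `"fall"`.
#'
#' @param stream A [sensor_stream()].
#' @param onset_s Fall onset time in seconds from stream start.
#' @param burst_s Impact-burst duration in seconds (about 0.5 s).
#' @param burst_gain Peak burst amplitude as a multiple of the pre-onset
#'   per-axis maximum (must be >= 3 for the burst to dominate the gait).
#' @param seed Integer seed for the burst/rest noise.
#' @return List with elements `stream` (modified) and `annotation`
#'   (`fall_annotation`: `onset_index`, `burst_duration`, `label_track`).
#' @export
inject_fall <- function(stream, onset_s, burst_s = 0.5, burst_gain = 3.5,
                        seed = 1L) {
  stopifnot(inherits(stream, "sensor_stream"))
  n <- ncol(stream$axes)
  rate <- stream$rate_hz
  onset <- round(onset_s * rate) + 1L
  burst_n <- max(2L, round(burst_s * rate))
  if (burst_gain < 3) stop("burst_gain must be >= 3", call. = FALSE)
  if (onset < 2L || onset + burst_n - 1L > n)
    stop(sprintf("fall onset %.2fs out of range for a %.2fs stream (burst %.2fs)",
                 onset_s, n / rate, burst_s), call. = FALSE)
  pre_max <- apply(abs(stream$axes[, seq_len(onset - 1L), drop = FALSE]), 1, max)
  pre_max[pre_max == 0] <- 1
  burst_idx <- onset:(onset + burst_n - 1L)
  rest_idx <- if (onset + burst_n <= n) (onset + burst_n):n else integer(0)
  env <- sin(pi * seq(0, 1, length.out = burst_n))^0.5  # impact envelope
  axes <- stream$axes
  with_seed(seed, {
    for (a in 1:3) {
      w <- env * stats::rnorm(burst_n)
      w <- w / max(abs(w)) * burst_gain * pre_max[a]
      axes[a, burst_idx] <- w
      if (length(rest_idx))
        axes[a, rest_idx] <- stats::rnorm(length(rest_idx),
                                          sd = 0.02 * pre_max[a])
    }
  })
  label <- rep("normal", n)
  label[onset:n] <- "fall"
  out <- stream
  out$axes <- axes
  list(stream = out,
       annotation = structure(list(onset_index = onset,
                                   burst_duration = burst_n,
                                   label_track = label),
                              class = "fall_annotation"))
}

#' Write a fall annotation as CSV (`index,label`)
#' @param annotation A `fall_annotation`.
#' @param path Output file path.
#' @export
write_fall_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "fall_annotation"))
  utils::write.csv(data.frame(index = seq_along(annotation$label_track),
                              label = annotation$label_track),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
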