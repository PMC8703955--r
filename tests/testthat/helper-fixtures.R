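# Small deterministic fixtures shared across test files.

# a clean one-harmonic profile with known frequency, built from a drawn
# profile so all invariants of the constructor hold
unit_profile <- function(f0 = 1, amps = list(1, 1, 1), noise = 0) {
  p <- make_subject_profile("unit", "walking", seed = 99, noise_sd = noise)
  p$fundamental_freq <- f0
  p$harmonic_amplitudes <- amps
  p$harmonic_phases <- list(0, 0, 0)
  p
}

# tiny encoded dataset on an 11x11 grid (Tw = 2) for fast model tests
tiny_dataset <- function(n_seconds = 12, tw = 2L) {
  p <- make_subject_profile("tiny", "walking", seed = 42)
  s <- generate_motion_stream(p, n_seconds, 30)
  encode_dataset(s, encoding_config(window_size = tw),
                 subject_id = "tiny", motion = "walking")
}

tiny_fno_config <- function() fno_config(num_layers = 2L, width = 4L,
                                         modes = 3L)

expect_all_close <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
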