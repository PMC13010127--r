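# Shared fixtures: small phantoms and a fast registration configuration so
# the default test run stays light; the acceptance tests use the full-size
# protocol.

fast_reg <- list(alpha = 2, n_iter = 60L, n_levels = 2L, n_warp = 2L)

small_spec <- function(n_frames = 120L, ...) {
  phantom_spec(grid_shape = c(64L, 64L), n_frames = n_frames, ...)
}

fast_config <- function(...) {
  run_config(registration = fast_reg, ...)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# resp_signal constructed directly (bypassing extraction) for unit tests of
# the reference-frame rule
make_resp_signal <- function(smoothed, peaks, troughs,
                             frame_interval_s = 0.3) {
  n <- length(smoothed)
  structure(list(raw = smoothed, smoothed = smoothed, peaks = peaks,
                 troughs = troughs, phase = rep(NA_real_, n),
                 times = (seq_len(n) - 1) * frame_interval_s,
                 resp_freq_hz = NA_real_),
            class = "resp_signal")
}
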