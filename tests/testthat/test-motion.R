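test_that("zero-lag low-pass keeps a slow sinusoid and removes a fast one", {
  fs <- 1 / 0.3
  t <- (0:299) * 0.3
  slow <- sin(2 * pi * 0.25 * t)
  fast <- 0.8 * sin(2 * pi * 1.2 * t)
  y <- lowpass_zero_lag(slow + fast, fs = fs, cutoff_hz = 0.5)
  mid <- 30:270 # away from the (padded) edges
  expect_lt(max(abs(y[mid] - slow[mid])), 0.06)
  # zero lag: cross-correlation peak of output vs input at lag 0
  cc <- stats::ccf(y[mid], slow[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("respiratory signal extraction recovers frequency and breath count", {
  ph <- generate_phantom(small_spec(seed = 2, noise_sigma = 0.3))
  cm <- coarse_lung_mask(ph$series)
  rs <- extract_respiratory_signal(ph$series, cm)
  expect_equal(rs$resp_freq_hz, 0.25, tolerance = 0.05)
  # 120 frames * 0.3 s = 36 s at 4 s/breath: 8-9 interior peaks
  expect_gte(length(rs$peaks), 7L)
  expect_lte(length(rs$peaks), 10L)
  # phase is in [0, 1) and restarts at each end-expiration peak
  ok <- !is.na(rs$phase)
  expect_true(all(rs$phase[ok] >= 0 & rs$phase[ok] < 1))
  expect_true(all(abs(rs$phase[rs$peaks]) < 1e-9, na.rm = TRUE))
})

test_that("too-short series yields an informative breath-count error", {
  ph <- generate_phantom(small_spec(n_frames = 12L))
  cm <- coarse_lung_mask(ph$series)
  expect_error(extract_respiratory_signal(ph$series, cm),
               "breath|peaks")
})

test_that("mid-expiration frame follows the worked descending-limb rule", {
  # end-expiration high, end-inspiration low; peak at index 6 (value 1.0),
  # mid level (1.0 + 0.0)/2 = 0.5; descending limb after the peak crosses
  # 0.5 nearest at value 0.59 -> index 9 (1-based)
  sm <- c(0, 0.31, 0.59, 0.81, 0.95, 1.0, 0.95, 0.81, 0.59, 0.31, 0)
  rs <- make_resp_signal(sm, peaks = 6L, troughs = c(1L, 11L))
  expect_identical(select_mid_expiration_frame(rs), 9L)
})

test_that("mid-expiration frame ties resolve to the earliest candidate", {
  sm <- c(0, 0.5, 1, 0.5, 0, 0.5, 1, 0.5, 0)
  rs <- make_resp_signal(sm, peaks = c(3L, 7L), troughs = c(1L, 5L, 9L))
  expect_identical(select_mid_expiration_frame(rs), 4L)
})

test_that("frequency-domain band filter isolates the cardiac component", {
  fs <- 1 / 0.3
  nt <- 240L
  t <- (seq_len(nt) - 1) * 0.3
  resp <- 3 * sin(2 * pi * 0.25 * t)
  card <- 0.7 * sin(2 * pi * 1.2 * t)
  arr <- array(0, c(4, 4, nt))
  for (i in 1:4) for (j in 1:4) arr[i, j, ] <- 50 + resp + card
  out <- temporal_filter_array(arr, fs = fs, low_hz = 0.6, high_hz = 1.6)
  rec <- out[2, 3, ]
  # without isolation the respiratory leakage alone would give NRMSE > 4;
  # the bound allows the filter's own passband droop at 1.2 Hz (zero-phase
  # filtering squares the magnitude response). A uniform gain at the cardiac
  # fundamental cancels in the downstream blood-region normalization.
  expect_lt(sqrt(mean((rec - card)^2)) / sqrt(mean(card^2)), 0.15)
  lp <- temporal_lowpass_array(arr, fs = fs, cutoff_hz = 0.6)
  expect_lt(sqrt(mean((lp[2, 3, ] - (50 + resp))^2)), 0.15)
})

test_that("registration of a motionless series leaves frames untouched", {
  ph <- generate_phantom(small_spec(diaphragm_motion_px = 0))
  cm <- coarse_lung_mask(ph$series)
  rs <- extract_respiratory_signal(ph$series, cm)
  ref <- select_mid_expiration_frame(rs)
  reg <- register_series(ph$series, ref, settings = fast_reg)
  expect_lt(mean(reg$mean_displacement_px), 0.1)
  expect_equal(reg$frames[, , ref], ph$series$frames[, , ref])
  expect_lt(mean(residual_displacement(reg, NULL, ph$truth$lung_mask)), 0.1)
})

test_that("registration removes most of a 3-pixel diaphragm excursion", {
  ph <- generate_phantom(small_spec(seed = 5, diaphragm_motion_px = 3))
  cm <- coarse_lung_mask(ph$series)
  rs <- extract_respiratory_signal(ph$series, cm)
  ref <- select_mid_expiration_frame(rs)
  reg <- register_series(ph$series, ref, settings = fast_reg)
  truth <- ph$truth$displacement_field_truth
  resid <- residual_displacement(reg, truth, ph$truth$lung_mask)
  # uncorrected motion relative to the same reference frame, for scale
  d_ref <- truth[, , ref]
  uncorrected <- vapply(seq_len(dim(truth)[3]), function(k) {
    mean(abs(truth[, , k] - d_ref)[ph$truth$lung_mask])
  }, numeric(1))
  expect_lt(mean(resid), 1.0)
  expect_lt(mean(resid), mean(uncorrected))
})

test_that("mask warping is nearest-neighbour and preserves binarity", {
  m <- matrix(FALSE, 16, 16); m[5:10, 5:10] <- TRUE
  u <- matrix(0.4, 16, 16); v <- matrix(-0.4, 16, 16)
  w <- warp_nearest(m, u, v)
  expect_type(w, "logical")
  expect_equal(sum(w), sum(m), tolerance = 8)
})
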