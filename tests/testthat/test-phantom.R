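test_that("phantom generation is deterministic for identical spec and seed", {
  spec <- small_spec(seed = 7, noise_sigma = 0.5,
                     diaphragm_motion_px = 2)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$series$frames, b$series$frames)
  expect_identical(a$truth$true_ventilation_map,
                   b$truth$true_ventilation_map)
  c <- generate_phantom(small_spec(seed = 8, noise_sigma = 0.5))
  expect_false(identical(a$series$frames, c$series$frames))
})

test_that("uniform ventilation amplitude gives the analytic truth value", {
  # a = 0.10 everywhere: RV = 100 * (1 - a/2) * a / (1 - a) = 10.5556%
  ph <- generate_phantom(small_spec(vent_amplitude = 0.10))
  vals <- ph$truth$true_ventilation_map[ph$truth$lung_mask]
  expect_equal(unique(round(vals, 10)), round(100 * 0.95 * 0.10 / 0.90, 10))
  expect_equal(vals[1], 10.5556, tolerance = 1e-4)
})

test_that("series duration and geometry follow the acquisition protocol", {
  spec <- phantom_spec() # defaults: 128x128, 250 frames at 0.3 s
  expect_equal(spec$n_frames, 250L)
  expect_equal(spec$frame_interval_s, 0.3)
  expect_equal((spec$n_frames - 1) * spec$frame_interval_s, 74.7)
  ph <- generate_phantom(small_spec())
  expect_equal(dim(ph$series$frames), c(64L, 64L, 120L))
})

test_that("signal model: expiration signal exceeds inspiration signal", {
  ph <- generate_phantom(small_spec())
  lung <- ph$truth$lung_mask & !ph$truth$blood_region_mask
  r <- ph$truth$resp_phase
  # frames nearest end-expiration (r ~ 0) vs end-inspiration (r ~ 0.5 phase)
  f_exp <- which.min(abs(r - 0))
  f_insp <- which.min(abs(r - 0.5))
  m_exp <- mean(ph$series$frames[, , f_exp][lung])
  m_insp <- mean(ph$series$frames[, , f_insp][lung])
  expect_gt(m_exp, m_insp)
})

test_that("invalid specs are rejected with informative errors", {
  expect_error(phantom_spec(cardiac_freq_hz = 1.7), "Nyquist")
  expect_error(phantom_spec(cardiac_freq_hz = 1/0.6), "Nyquist") # at Nyquist
  expect_error(phantom_spec(grid_shape = c(8, 128)), "degenerate")
  expect_error(phantom_spec(n_frames = 1), "n_frames")
  expect_error(phantom_spec(vent_amplitude = 1), "vent_amplitude")
  expect_error(
    phantom_spec(vent_defect_regions = list(
      defect_region("basal_fraction", fraction = 0.2, multiplier = 1.5))),
    "multiplier")
})

test_that("respiratory waveform hits range, period and phase origin", {
  expect_equal(resp_waveform(0, 0.25), 0)
  # quarter period of 0.25 Hz: (1 - cos(2*pi*0.5)) / 2 = 1 at t = 2 s
  expect_equal(resp_waveform(2, 0.25), 1)
  expect_equal(resp_waveform(1, 0.25), 0.5) # (1 - cos(pi/2)) / 2
  t <- seq(0, 20, by = 0.05)
  for (shape in c("sinusoid", "asymmetric")) {
    w <- resp_waveform(t, 0.25, shape)
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(resp_waveform(t, 0.25, shape),
                 resp_waveform(t + 4, 0.25, shape), tolerance = 1e-12)
  }
  # asymmetric: inspiration (trough -> peak) is shorter than expiration
  # (peak -> trough), so the peak sits well before mid-cycle
  tt <- seq(0, 4, length.out = 4001)[-4001]
  w <- resp_waveform(tt, 0.25, "asymmetric")
  expect_lt(tt[which.max(w)], 0.45 * 4)
  expect_error(resp_waveform(1, 0), "positive")
})

test_that("defect regions stay inside the lung and cover exact fractions", {
  ph <- generate_phantom(small_spec())
  lung <- ph$truth$lung_mask
  expect_equal(sum(insert_defect_regions(lung, list())), 0)
  reg <- list(defect_region("basal_fraction", fraction = 0.2,
                            multiplier = 0.1))
  m1 <- insert_defect_regions(lung, reg, seed = 3)
  m2 <- insert_defect_regions(lung, reg, seed = 3)
  expect_identical(m1, m2)
  expect_true(all(lung[m1]))
  expect_identical(sum(m1), as.integer(round(0.2 * sum(lung))))
  # analytic ellipse: area fraction within voxel quantization
  ell <- list(defect_region("ellipse", center = c(26, 36),
                            semi_axes = c(8, 10), multiplier = 0))
  me <- insert_defect_regions(lung, ell)
  expect_true(all(lung[me]))
  expect_warning(
    insert_defect_regions(lung, list(defect_region(
      "ellipse", center = c(2, 2), semi_axes = c(1, 1), multiplier = 0))),
    "outside")
})

test_that("ground-truth masks are disjoint where required", {
  spec <- small_spec(vent_defect_regions = list(
    defect_region("basal_fraction", fraction = 0.25, multiplier = 0)))
  ph <- generate_phantom(spec)
  expect_false(any(ph$truth$blood_region_mask & ph$truth$lung_mask))
  expect_true(all(ph$truth$lung_mask[ph$truth$vent_defect_mask]))
  expect_equal(ph$truth$vent_defect_fraction, 0.25,
               tolerance = 2 / sum(ph$truth$lung_mask))
})
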