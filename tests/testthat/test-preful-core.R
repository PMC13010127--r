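make_cycle <- function(values, mask = NULL) {
  d <- dim(values)
  structure(list(values = values,
                 occupancy = rep(1L, d[3]),
                 interpolated = rep(FALSE, d[3]),
                 n_bins = d[3],
                 mask = mask %||% matrix(TRUE, d[1], d[2])),
            class = "phase_cycle")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cardiac phase extraction recovers frequency and advance rate", {
  nt <- 240L; dt <- 0.3
  t <- (seq_len(nt) - 1) * dt
  sig <- 80 + 10 * sin(2 * pi * 1.2 * t)
  frames <- array(rep(sig, each = 16), c(4, 4, nt))
  s <- image_series(frames, frame_interval_s = dt)
  seed <- matrix(TRUE, 4, 4)
  card <- extract_cardiac_phase(s, seed)
  expect_equal(card$frequency_hz, 1.2, tolerance = 1 / (nt * dt) + 1e-9)
  # phase advances by dt * f per frame (mod 1), away from filter edges
  dph <- diff(card$phase[30:200]) %% 1
  expect_equal(median(dph), (dt * 1.2) %% 1, tolerance = 0.01)
})

test_that("respiratory-only signals are rejected as non-cardiac", {
  nt <- 240L; dt <- 0.3
  t <- (seq_len(nt) - 1) * dt
  sig <- 80 + 10 * sin(2 * pi * 0.25 * t)
  frames <- array(rep(sig, each = 16), c(4, 4, nt))
  s <- image_series(frames, frame_interval_s = dt)
  expect_error(extract_cardiac_phase(s, matrix(TRUE, 4, 4)),
               "no cardiac signal")
})

test_that("phase-bin reconstruction equals the brute-force oracle", {
  set.seed(11)
  nt <- 30L
  frames <- array(rnorm(4 * 4 * nt, 50, 5), c(4, 4, nt))
  s <- image_series(frames, frame_interval_s = 0.3)
  phases <- runif(nt)
  phases[c(3, 17)] <- NA
  mask <- matrix(TRUE, 4, 4)
  n_bins <- 5L
  cyc <- reconstruct_cycle(s, phases, mask, n_bins)
  # brute force: per voxel, per bin, mean over frames assigned by floor rule
  for (i in 1:4) for (j in 1:4) for (b in seq_len(n_bins)) {
    fr <- which(!is.na(phases) &
                  pmin(floor(phases * n_bins), n_bins - 1L) + 1L == b)
    if (length(fr)) {
      expect_identical(cyc$values[i, j, b], mean(frames[i, j, fr]))
    }
  }
})

test_that("worked phase assignment: six frames into three bins pairwise", {
  phases <- c(0, .17, .34, .51, .68, .85)
  frames <- array(0, c(1, 1, 6))
  frames[1, 1, ] <- c(10, 20, 30, 40, 50, 60)
  s <- image_series(frames, frame_interval_s = 0.3)
  cyc <- reconstruct_cycle(s, phases, matrix(TRUE, 1, 1), n_bins = 5L)
  # floor(phase*5): 0,0,1,2,3,4 -> bins {1,2},{3},{4},{5},{6}
  expect_equal(cyc$values[1, 1, 1], 15)
  expect_equal(cyc$values[1, 1, 2], 30)
  expect_equal(cyc$occupancy, c(2L, 1L, 1L, 1L, 1L))
})

test_that("bin-edge phases follow the floor convention", {
  phases <- c(0, 0.2, 0.4, 0.6, 0.8) # each exactly at a bin edge, n_bins=5
  frames <- array(seq_len(5), c(1, 1, 5))
  s <- image_series(frames, frame_interval_s = 0.3)
  cyc <- reconstruct_cycle(s, phases, matrix(TRUE, 1, 1), n_bins = 5L)
  expect_equal(as.numeric(cyc$values[1, 1, ]), 1:5)
  expect_true(all(cyc$occupancy == 1L))
})

test_that("constant series reconstructs to a constant cycle", {
  frames <- array(7, c(2, 2, 20))
  s <- image_series(frames, frame_interval_s = 0.3)
  cyc <- reconstruct_cycle(s, seq(0, 0.95, length.out = 20),
                           matrix(TRUE, 2, 2), n_bins = 5L)
  expect_true(all(cyc$values == 7))
})

test_that("sparse phase coverage is rejected above the empty-bin budget", {
  frames <- array(rnorm(4 * 4 * 20), c(4, 4, 20))
  s <- image_series(frames, frame_interval_s = 0.3)
  # all phases in [0, 0.2): 12 of 15 bins empty
  expect_error(reconstruct_cycle(s, runif(20, 0, 0.19),
                                 matrix(TRUE, 4, 4), n_bins = 15L),
               "insufficient phase coverage")
})

test_that("empty bins within budget are interpolated circularly and flagged", {
  phases <- c(0.05, 0.05, 0.25, 0.45, 0.85) # bin 4 of 5 empty
  frames <- array(0, c(1, 1, 5))
  frames[1, 1, ] <- c(10, 20, 30, 40, 50)
  s <- image_series(frames, frame_interval_s = 0.3)
  cyc <- reconstruct_cycle(s, phases, matrix(TRUE, 1, 1), n_bins = 5L)
  expect_identical(cyc$interpolated, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  # neighbours: bin 3 (value 40) at distance 1, bin 5 (value 50) at 1
  expect_equal(cyc$values[1, 1, 4], 45)
})

test_that("ventilation formula reproduces the worked value 20.20%", {
  v <- array(0, c(1, 1, 3))
  v[1, 1, ] <- c(90, 100, 110) # S_insp (min) = 90, S_exp (max) = 110
  cyc <- make_cycle(v)
  m <- compute_ventilation_map(cyc, mid_bin = 2L) # S_mid = 100
  expect_equal(m$values[1, 1], 100 * (100 / 90 - 100 / 110))
  expect_equal(m$values[1, 1], 20.2, tolerance = 0.005)
})

test_that("no modulation means zero ventilation, not no-data", {
  v <- array(100, c(1, 1, 5))
  m <- compute_ventilation_map(make_cycle(v), mid_bin = 3L)
  expect_equal(m$values[1, 1], 0)
})

test_that("non-positive inspiration signal is marked no-data", {
  v <- array(0, c(2, 1, 3))
  v[1, 1, ] <- c(-5, 10, 20)
  v[2, 1, ] <- c(5, 10, 20)
  m <- compute_ventilation_map(make_cycle(v), mid_bin = 2L)
  expect_true(is.na(m$values[1, 1]))
  expect_false(is.na(m$values[2, 1]))
  expect_error(compute_ventilation_map(make_cycle(v), mid_bin = 9L),
               "mid_bin")
})

test_that("perfusion normalization: ratio arithmetic and blood identity", {
  v <- array(0, c(2, 2, 4))
  v[1, 1, ] <- c(0, 50, 0, 50)     # amplitude 50 (blood)
  v[2, 1, ] <- c(10, 15, 10, 15)   # amplitude 5
  v[1, 2, ] <- c(7, 7, 7, 7)       # amplitude 0
  v[2, 2, ] <- c(0, 25, 0, 25)     # amplitude 25
  blood <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  m <- compute_perfusion_map(make_cycle(v), blood)
  expect_equal(m$values[2, 1], 10)   # 100 * 5 / 50
  expect_equal(m$values[1, 2], 0)
  expect_equal(m$values[1, 1], 100)  # blood voxel itself
  expect_equal(mean(m$values[blood]), 100) # normalization identity
  # zero blood amplitude rejected
  vz <- array(1, c(2, 2, 4))
  expect_error(compute_perfusion_map(make_cycle(vz), blood),
               "zero cardiac amplitude")
})

test_that("healthy region selects the 80th-90th percentile band", {
  # 100 voxels valued 1..100 laid out in raster order on a 10x10 grid:
  # P80 = 80.2, P90 = 90.1 (linear interpolation), so values 81..90 qualify
  vals <- matrix(as.numeric(1:100), 10, 10)
  expect_equal(quantile(1:100, 0.8, type = 7, names = FALSE), 80.2)
  expect_equal(quantile(1:100, 0.9, type = 7, names = FALSE), 90.1)
  m <- quant_map(vals, "ventilation_pct", matrix(TRUE, 10, 10))
  region <- healthy_reference_region(m)
  expect_identical(sort(vals[region]), as.numeric(81:90))
  # 81..90 occupy a single column -> one connected component
  expect_equal(sum(region), 10L)
})

test_that("all-equal ventilation selects the whole lung as reference", {
  vals <- matrix(5, 6, 6)
  m <- quant_map(vals, "ventilation_pct", matrix(TRUE, 6, 6))
  expect_true(all(healthy_reference_region(m)))
  tiny <- quant_map(matrix(5, 2, 2), "ventilation_pct", matrix(TRUE, 2, 2))
  expect_error(healthy_reference_region(tiny), "few")
})

test_that("FVL correlation: identity, negation and quadrature", {
  nb <- 15L
  b <- seq_len(nb)
  base <- 100 + 10 * sin(2 * pi * (b - 1) / nb)
  anti <- 100 - 10 * sin(2 * pi * (b - 1) / nb)
  quad <- 100 + 10 * cos(2 * pi * (b - 1) / nb)
  v <- array(0, c(2, 2, nb))
  v[1, 1, ] <- base
  v[2, 1, ] <- base * 3 + 7   # affine copy: r = 1 regardless of scale
  v[1, 2, ] <- anti
  v[2, 2, ] <- quad
  cyc <- make_cycle(v)
  ref <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  m <- compute_fvl_correlation_map(cyc, ref)
  expect_equal(m$values[1, 1], 1)
  expect_equal(m$values[2, 1], 1)
  expect_equal(m$values[1, 2], -1)
  expect_lt(abs(m$values[2, 2]), 1e-12)
})

test_that("zero-variance voxels carry the no-data marker in the FVL map", {
  nb <- 15L
  b <- seq_len(nb)
  v <- array(0, c(2, 1, nb))
  v[1, 1, ] <- 100 + 10 * sin(2 * pi * (b - 1) / nb)
  v[2, 1, ] <- 42
  cyc <- make_cycle(v)
  m <- compute_fvl_correlation_map(cyc, matrix(c(TRUE, FALSE), 2, 1))
  expect_true(is.na(m$values[2, 1]))
})
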