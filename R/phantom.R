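#' Specification of a dynamic lung MRI phantom
#'
#' Parameterizes a free-breathing 2D+t coronal lung phantom: two elliptical
#' lungs inside a body ellipse with a small high-signal disc (aorta, the
#' full-blood reference) between them. Parenchymal signal is compressed over
#' the respiratory cycle (proton-density dilution on inspiration, so signal
#' is highest at end-expiration), blood-supplied voxels pulse over the
#' cardiac cycle, and the lower lung can be displaced vertically to emulate
#' diaphragm motion. Defaults emulate a bSSFP free-breathing protocol:
#' 128x128 matrix, 250 frames at 300 ms (74.7 s first-to-last).
#'
#' @param grid_shape integer pair, in-plane matrix size (default `c(128, 128)`).
#' @param n_frames number of time points (default 250).
#' @param frame_interval_s temporal resolution in seconds (default 0.3).
#' @param resp_freq_hz respiratory frequency in Hz (default 0.25).
#' @param cardiac_freq_hz cardiac frequency in Hz (default 1.2); must be
#'   below Nyquist `1/(2 * frame_interval_s)`.
#' @param vent_amplitude fractional parenchymal signal compression `a` in
#'   `[0, 1)` at end-inspiration (default 0.10).
#' @param perf_amplitude_lung cardiac-cycle signal amplitude of lung
#'   parenchyma, signal units (default 1).
#' @param perf_amplitude_blood cardiac-cycle amplitude of the full-blood disc
#'   (default 10), so healthy normalized perfusion is ~10%.
#' @param baseline_signal named list of tissue baselines (background, body,
#'   lung, blood), signal units.
#' @param vent_defect_regions,perf_defect_regions lists of region descriptors
#'   (see [defect_region()]); each carries an amplitude multiplier in `[0, 1]`.
#' @param diaphragm_motion_px peak downward displacement of the lung base at
#'   end-inspiration, pixels (default 0).
#' @param resp_shape respiratory waveform shape, `"sinusoid"` or
#'   `"asymmetric"`.
#' @param noise_sigma additive Gaussian noise standard deviation, signal
#'   units (default 0).
#' @param noise_model `"gaussian"` (default) or `"rician"`
#'   (magnitude-image noise).
#' @param pixel_spacing_mm in-plane voxel spacing (default 1.7 mm).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L),
                         n_frames = 250L,
                         frame_interval_s = 0.3,
                         resp_freq_hz = 0.25,
                         cardiac_freq_hz = 1.2,
                         vent_amplitude = 0.10,
                         perf_amplitude_lung = 1.0,
                         perf_amplitude_blood = 10.0,
                         baseline_signal = list(background = 5, body = 60,
                                                lung = 35, blood = 80),
                         vent_defect_regions = list(),
                         perf_defect_regions = list(),
                         diaphragm_motion_px = 0,
                         resp_shape = c("sinusoid", "asymmetric"),
                         noise_sigma = 0,
                         noise_model = c("gaussian", "rician"),
                         pixel_spacing_mm = c(1.7, 1.7),
                         seed = 1L) {
  spec <- list(
    grid_shape = as.integer(grid_shape), n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s, resp_freq_hz = resp_freq_hz,
    cardiac_freq_hz = cardiac_freq_hz, vent_amplitude = vent_amplitude,
    perf_amplitude_lung = perf_amplitude_lung,
    perf_amplitude_blood = perf_amplitude_blood,
    baseline_signal = baseline_signal,
    vent_defect_regions = vent_defect_regions,
    perf_defect_regions = perf_defect_regions,
    diaphragm_motion_px = diaphragm_motion_px,
    resp_shape = match.arg(resp_shape),
    noise_sigma = noise_sigma, noise_model = match.arg(noise_model),
    pixel_spacing_mm = pixel_spacing_mm, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$grid_shape < 16L))
    stop2("degenerate grid: each side must be >= 16 px")
  if (spec$n_frames < 2L) stop2("n_frames must be >= 2")
  if (spec$frame_interval_s <= 0) stop2("frame_interval_s must be > 0")
  nyquist <- 1 / (2 * spec$frame_interval_s)
  if (spec$cardiac_freq_hz >= nyquist)
    stop2(sprintf(
      "cardiac_freq_hz (%.3g Hz) is at or above the Nyquist frequency %.3g Hz for a %.3g s frame interval; the cardiac cycle would alias and cannot be phase-resolved",
      spec$cardiac_freq_hz, nyquist, spec$frame_interval_s))
  if (spec$resp_freq_hz <= 0) stop2("resp_freq_hz must be > 0")
  if (spec$vent_amplitude < 0 || spec$vent_amplitude >= 1)
    stop2("vent_amplitude must be in [0, 1)")
  for (r in c(spec$vent_defect_regions, spec$perf_defect_regions)) {
    m <- r$multiplier %||% 0
    if (m < 0 || m > 1) stop2("defect amplitude multipliers must be in [0, 1]")
  }
  if (spec$noise_sigma < 0) stop2("noise_sigma must be >= 0")
  invisible(spec)
}

#' Respiratory waveform
#'
#' Periodic waveform in `[0, 1]` parameterizing the respiratory cycle:
#' 0 = end-expiration, 1 = end-inspiration. The `"asymmetric"` variant
#' spends more of the cycle in expiration than inspiration, as in quiet
#' breathing.
#'
#' @param t time in seconds (vectorized).
#' @param freq frequency in Hz (> 0).
#' @param shape `"sinusoid"` or `"asymmetric"`.
#' @return numeric vector in `[0, 1]`, period `1/freq`, value 0 at `t = 0`.
#' @export
resp_waveform <- function(t, freq, shape = c("sinusoid", "asymmetric")) {
  shape <- match.arg(shape)
  if (!is.numeric(freq) || length(freq) != 1L || freq <= 0)
    stop2("freq must be a positive scalar (Hz)")
  phase <- (t * freq) %% 1
  if (shape == "sinusoid") {
    (1 - cos(2 * pi * phase)) / 2
  } else {
    # inspiration occupies the first 35% of the cycle, expiration the rest
    ti <- 0.35
    ifelse(phase < ti,
           (1 - cos(pi * phase / ti)) / 2,
           (1 + cos(pi * (phase - ti) / (1 - ti))) / 2)
  }
}

# Cardiac inflow waveform in [0, 1]; raised cosine, peak inflow mid-cycle.
cardiac_waveform <- function(t, freq) {
  (1 - cos(2 * pi * ((t * freq) %% 1))) / 2
}

#' Describe a defect region for the phantom
#'
#' @param shape `"ellipse"` (explicit geometry) or `"basal_fraction"` (the
#'   basal portion of the lung mask covering an exact voxel fraction,
#'   selected by descending row so the defect sits at the lung base).
#' @param center,semi_axes ellipse center (x, y) and semi-axes in pixels
#'   (shape = "ellipse").
#' @param fraction fraction of lung voxels to cover (shape =
#'   "basal_fraction").
#' @param multiplier amplitude multiplier in `[0, 1]` applied inside the
#'   region (0 = complete defect).
#' @return a region descriptor list.
#' @export
defect_region <- function(shape = c("ellipse", "basal_fraction"),
                          center = NULL, semi_axes = NULL,
                          fraction = NULL, multiplier = 0) {
  shape <- match.arg(shape)
  if (shape == "ellipse" && (is.null(center) || is.null(semi_axes)))
    stop2("ellipse regions need center and semi_axes")
  if (shape == "basal_fraction" &&
      (is.null(fraction) || fraction <= 0 || fraction >= 1))
    stop2("basal_fraction regions need fraction in (0, 1)")
  list(shape = shape, center = center, semi_axes = semi_axes,
       fraction = fraction, multiplier = multiplier)
}

ellipse_mask <- function(grid_shape, center, semi_axes) {
  x <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  y <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2],
              byrow = TRUE)
  ((x - center[1]) / semi_axes[1])^2 + ((y - center[2]) / semi_axes[2])^2 <= 1
}

#' Rasterize defect regions inside a lung mask
#'
#' @param mask logical lung mask.
#' @param regions list of [defect_region()] descriptors.
#' @param seed integer seed (kept for reproducibility of any stochastic
#'   region types; current shapes are deterministic).
#' @return logical defect mask, always a subset of `mask`.
#' @export
insert_defect_regions <- function(mask, regions, seed = 1L) {
  out <- mask & FALSE
  if (length(regions) == 0L) return(out)
  gs <- dim(mask)
  for (r in regions) {
    if (r$shape == "ellipse") {
      em <- ellipse_mask(gs, r$center, r$semi_axes)
      hit <- em & mask
      if (!any(hit))
        warning("defect region lies fully outside the lung mask; ignored")
      out <- out | hit
    } else { # basal_fraction: exact voxel count, basal rows first
      n_target <- round(r$fraction * sum(mask))
      idx <- which(mask, arr.ind = TRUE)
      ord <- order(-idx[, 2], idx[, 1]) # descending y (base first), then x
      take <- idx[ord[seq_len(n_target)], , drop = FALSE]
      out[cbind(take[, 1], take[, 2])] <- TRUE
    }
  }
  out & mask
}

# Default anatomy (in units of the grid): body ellipse, two lung ellipses,
# aortic disc centred between them.
phantom_anatomy <- function(grid_shape) {
  cx <- (grid_shape[1] + 1) / 2
  cy <- (grid_shape[2] + 1) / 2
  s <- grid_shape / 128 # scale anatomy with the grid
  body <- list(center = c(cx, cy), semi_axes = c(55, 60) * s)
  lung_l <- list(center = c(cx - 26 * s[1], cy - 4 * s[2]),
                 semi_axes = c(18, 32) * s)
  lung_r <- list(center = c(cx + 26 * s[1], cy - 4 * s[2]),
                 semi_axes = c(18, 32) * s)
  blood <- list(center = c(cx, cy - 4 * s[2]), radius = 5 * min(s))
  list(body = body, lung_l = lung_l, lung_r = lung_r, blood = blood)
}

#' Generate a dynamic lung phantom with analytic ground truth
#'
#' Builds the 2D+t series `S(x, t)`: inside the lungs
#' `S = S0 * (1 - a(x) * r(t)) + A_q(x) * c(t)` (proton-density compression on
#' inspiration plus cardiac inflow), in the blood disc
#' `S = S0 + A_q * c(t)`, elsewhere static tissue baselines; optional
#' diaphragm motion warps the lower lung vertically by
#' `diaphragm_motion_px * r(t)` (ramped from lung apex to base) and optional
#' noise is added last. The returned ground truth carries the analytic
#' regional-ventilation map `100 * (1 - a/2) * a / (1 - a)`, the perfusion
#' amplitude map, true masks, per-frame respiratory/cardiac phases and the
#' per-frame displacement truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `series` (an `image_series`) and `truth` (a
#'   `phantom_truth` list).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  gs <- spec$grid_shape
  ana <- phantom_anatomy(gs)
  body <- ellipse_mask(gs, ana$body$center, ana$body$semi_axes)
  lung_l <- ellipse_mask(gs, ana$lung_l$center, ana$lung_l$semi_axes)
  lung_r <- ellipse_mask(gs, ana$lung_r$center, ana$lung_r$semi_axes)
  lung <- lung_l | lung_r
  blood <- ellipse_mask(gs, ana$blood$center, rep(ana$blood$radius, 2)) & !lung
  stopifnot(!any(blood & lung))

  # amplitude fields
  vent_defect <- insert_defect_regions(lung, spec$vent_defect_regions,
                                       spec$seed)
  perf_defect <- insert_defect_regions(lung, spec$perf_defect_regions,
                                       spec$seed + 1L)
  a_map <- matrix(0, gs[1], gs[2])
  a_map[lung] <- spec$vent_amplitude
  for (r in spec$vent_defect_regions) {
    dm <- insert_defect_regions(lung, list(r), spec$seed)
    a_map[dm] <- spec$vent_amplitude * r$multiplier
  }
  q_map <- matrix(0, gs[1], gs[2])
  q_map[lung] <- spec$perf_amplitude_lung
  for (r in spec$perf_defect_regions) {
    dm <- insert_defect_regions(lung, list(r), spec$seed + 1L)
    q_map[dm] <- spec$perf_amplitude_lung * r$multiplier
  }
  q_map[blood] <- spec$perf_amplitude_blood

  s0 <- matrix(spec$baseline_signal$background, gs[1], gs[2])
  s0[body] <- spec$baseline_signal$body
  s0[lung] <- spec$baseline_signal$lung
  s0[blood] <- spec$baseline_signal$blood

  tvec <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval_s
  r_t <- resp_waveform(tvec, spec$resp_freq_hz, spec$resp_shape)
  c_t <- cardiac_waveform(tvec, spec$cardiac_freq_hz)

  # vertical displacement weight: 0 at the lung apex, 1 at the lung base
  y <- matrix(seq_len(gs[2]), gs[1], gs[2], byrow = TRUE)
  lung_rows <- range(which(apply(lung, 2, any)))
  w <- pmin(pmax((y - lung_rows[1]) / diff(lung_rows), 0), 1)
  w[y > lung_rows[2]] <- pmax(0, 1 - (y[y > lung_rows[2]] - lung_rows[2]) /
                                 (0.25 * gs[2]))

  frames <- array(0, c(gs[1], gs[2], spec$n_frames))
  disp <- if (spec$diaphragm_motion_px != 0)
    array(0, c(gs[1], gs[2], spec$n_frames)) else NULL
  for (k in seq_len(spec$n_frames)) {
    m <- s0 * (1 - a_map * r_t[k]) + q_map * c_t[k]
    if (spec$diaphragm_motion_px != 0) {
      d <- spec$diaphragm_motion_px * r_t[k]
      # pull-back: spatial voxel (x, y) shows material point (x, y - d*w)
      frames[, , k] <- warp_bilinear(m, matrix(0, gs[1], gs[2]), -d * w)
      disp[, , k] <- d * w
    } else {
      frames[, , k] <- m
    }
  }
  if (spec$noise_sigma > 0) {
    frames <- with_seed(spec$seed, {
      if (spec$noise_model == "gaussian") {
        frames + array(rnorm(length(frames), 0, spec$noise_sigma), dim(frames))
      } else {
        re <- frames + array(rnorm(length(frames), 0, spec$noise_sigma),
                             dim(frames))
        im <- array(rnorm(length(frames), 0, spec$noise_sigma), dim(frames))
        sqrt(re^2 + im^2)
      }
    })
  }

  a <- spec$vent_amplitude
  true_rv <- matrix(NA_real_, gs[1], gs[2])
  true_rv[lung] <- 100 * (1 - a_map[lung] / 2) * a_map[lung] /
    (1 - a_map[lung])

  series <- image_series(frames, pixel_spacing_mm = spec$pixel_spacing_mm,
                         frame_interval_s = spec$frame_interval_s,
                         identifier = sprintf("phantom-seed%d", spec$seed))
  truth <- structure(list(
    lung_mask = lung, blood_region_mask = blood,
    true_ventilation_map = true_rv,
    true_perfusion_amplitude_map = q_map,
    vent_defect_mask = vent_defect, perf_defect_mask = perf_defect,
    vent_defect_fraction = sum(vent_defect) / sum(lung),
    perf_defect_fraction = sum(perf_defect) / sum(lung),
    resp_phase = (tvec * spec$resp_freq_hz) %% 1,
    cardiac_phase = (tvec * spec$cardiac_freq_hz) %% 1,
    displacement_field_truth = disp,
    spec = spec), class = "phantom_truth")
  list(series = series, truth = truth)
}
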