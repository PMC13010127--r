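# Phase-resolved cycle reconstruction and the three voxel-wise maps:
# regional ventilation (%), normalized perfusion (%) and flow-volume-loop
# correlation.

#' Extract the cardiac phase from a blood seed region
#'
#' The seed-region mean signal is band-pass filtered (zero-lag Butterworth);
#' the dominant cardiac frequency is the spectral magnitude peak within the
#' band, which must stand clearly above the in-band noise floor; the
#' instantaneous phase comes from the analytic-signal angle, shifted so that
#' phase 0 sits at band-passed-signal maxima (peak inflow).
#'
#' @param registered a `registered_series` (or [image_series()]).
#' @param blood_seed logical matrix, non-empty.
#' @param band_hz cardiac band in Hz (default 0.6-2.0); clipped to Nyquist.
#' @param peak_ratio_min minimum ratio of the spectral peak to the median
#'   in-band magnitude for a cardiac signal to be accepted (default 8).
#' @return list: `phase` (per-frame, in `[0, 1)`), `frequency_hz`,
#'   `filtered` (band-passed seed signal).
#' @export
extract_cardiac_phase <- function(registered, blood_seed,
                                  band_hz = c(0.6, 2.0),
                                  peak_ratio_min = 8) {
  if (!any(blood_seed)) stop2("empty blood seed")
  fs <- 1 / registered$frame_interval_s
  nyq <- fs / 2
  band <- c(max(band_hz[1], 1e-3), min(band_hz[2], 0.98 * nyq))
  if (band[2] <= band[1]) stop2("cardiac band collapses below Nyquist")
  d <- dim(registered$frames)
  flat <- matrix(registered$frames, d[1] * d[2], d[3])
  x <- colMeans(flat[which(blood_seed), , drop = FALSE])
  x <- x - mean(x)
  nt <- length(x)
  sp <- Mod(fft(x))[seq_len(floor(nt / 2))]
  freqs <- (seq_len(floor(nt / 2)) - 1) * fs / nt
  inband <- freqs >= band[1] & freqs <= band[2]
  if (!any(inband)) stop2("no cardiac signal: empty spectral band")
  pk <- max(sp[inband])
  med <- median(sp[inband])
  if (med <= 0 || pk / med < peak_ratio_min || pk < 1e-10)
    stop2("no cardiac signal: no spectral peak above the noise floor in ",
          sprintf("%.2f-%.2f Hz", band[1], band[2]))
  f_card <- freqs[inband][which.max(sp[inband])]
  bf <- signal::butter(2, pmin(band / nyq, 0.99), type = "pass")
  xf <- filtfilt_padded(bf, x, pad = ceiling(4 * fs / band[1]))
  an <- analytic_signal(xf)
  phase <- (Arg(an) / (2 * pi)) %% 1
  list(phase = phase, frequency_hz = f_card, filtered = xf)
}

#' Reconstruct a phase-resolved cycle
#'
#' Each frame with a defined phase is assigned to bin
#' `floor(phase * n_bins)`; the per-voxel bin value is the mean over the
#' assigned frames. Empty bins are filled by circular linear interpolation
#' between the nearest occupied bins and flagged.
#'
#' @param registered a `registered_series` (or [image_series()]).
#' @param phases per-frame phase in `[0, 1)`; `NA` frames are excluded.
#' @param mask logical matrix; the cycle is defined only inside it.
#' @param n_bins number of phase bins (>= 5, default 15).
#' @return object of class `phase_cycle`: `values` (X x Y x n_bins array,
#'   `NA` outside mask), `occupancy` (frames per bin), `interpolated`
#'   (logical per bin), `n_bins`.
#' @export
reconstruct_cycle <- function(registered, phases, mask, n_bins = 15L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 5L) stop2("n_bins must be >= 5")
  d <- dim(registered$frames)
  usable <- which(!is.na(phases))
  if (length(usable) < n_bins) stop2("insufficient phase coverage: fewer usable frames than bins")
  ph <- phases[usable]
  stopifnot(all(ph >= 0 & ph < 1))
  bin <- pmin(floor(ph * n_bins), n_bins - 1L) + 1L
  occupancy <- tabulate(bin, nbins = n_bins)
  if (sum(occupancy == 0L) > 0.3 * n_bins)
    stop2("insufficient phase coverage: more than 30% of bins are empty")
  flat <- matrix(registered$frames, d[1] * d[2], d[3])
  idx <- which(mask)
  vals <- matrix(NA_real_, length(idx), n_bins)
  for (b in seq_len(n_bins)) {
    fr <- usable[bin == b]
    if (length(fr) == 0L) next
    vals[, b] <- rowMeans(flat[idx, fr, drop = FALSE])
  }
  interpolated <- occupancy == 0L
  if (any(interpolated)) {
    occ <- which(!interpolated)
    for (b in which(interpolated)) {
      # circular nearest occupied neighbours
      dist_l <- (b - occ) %% n_bins; dist_l[dist_l == 0] <- n_bins
      dist_r <- (occ - b) %% n_bins; dist_r[dist_r == 0] <- n_bins
      bl <- occ[which.min(dist_l)]; br <- occ[which.min(dist_r)]
      wl <- min(dist_r); wr <- min(dist_l) # inverse-distance weights
      vals[, b] <- (vals[, bl] * wl + vals[, br] * wr) / (wl + wr)
    }
  }
  out <- array(NA_real_, c(d[1], d[2], n_bins))
  for (b in seq_len(n_bins)) {
    slice <- matrix(NA_real_, d[1], d[2])
    slice[idx] <- vals[, b]
    out[, , b] <- slice
  }
  structure(list(values = out, occupancy = occupancy,
                 interpolated = interpolated, n_bins = n_bins, mask = mask),
            class = "phase_cycle")
}

#' Regional ventilation map
#'
#' Voxel-wise regional ventilation in percent from the reconstructed
#' respiratory cycle: `RV = 100 * (S_mid/S_insp - S_mid/S_exp)`, with
#' `S_insp` the cycle minimum (end-inspiration: proton-density dilution
#' lowers the signal), `S_exp` the cycle maximum (end-expiration) and
#' `S_mid` the value at the mid-expiration bin (the registration target's
#' phase bin). Voxels with non-positive `S_insp` are marked no-data.
#'
#' @param resp_cycle a `phase_cycle` over the respiratory phase.
#' @param mid_bin integer bin index (1-based) of the mid position.
#' @return a [quant_map()] of kind `"ventilation_pct"`.
#' @export
compute_ventilation_map <- function(resp_cycle, mid_bin) {
  nb <- resp_cycle$n_bins
  if (mid_bin < 1L || mid_bin > nb) stop2("mid_bin out of range")
  v <- resp_cycle$values
  r <- cycle_range(v)
  s_insp <- r$min
  s_exp <- r$max
  s_mid <- matrix(v[, , mid_bin], dim(v)[1], dim(v)[2])
  rv <- 100 * (s_mid / s_insp - s_mid / s_exp)
  rv[!is.na(s_insp) & s_insp <= 0] <- NA_real_
  rv[!resp_cycle$mask] <- NA_real_
  quant_map(rv, "ventilation_pct", resp_cycle$mask)
}

#' Normalized perfusion map
#'
#' Voxel-wise cardiac-cycle amplitude (peak-to-trough over the reconstructed
#' cardiac cycle) expressed as a percentage of the mean amplitude inside the
#' full-blood reference region: `Q = 100 * amplitude / amplitude_blood`.
#' The blood-region mean maps to 100% by construction.
#'
#' @param card_cycle a `phase_cycle` over the cardiac phase, defined on the
#'   union of the lung mask and the blood region.
#' @param blood_region logical matrix (the reference region).
#' @param mask optional logical matrix restricting the output map (defaults
#'   to the cycle's mask).
#' @return a [quant_map()] of kind `"perfusion_pct"`.
#' @export
compute_perfusion_map <- function(card_cycle, blood_region, mask = NULL) {
  v <- card_cycle$values
  r <- cycle_range(v)
  amp <- r$max - r$min
  ref <- mean(amp[blood_region], na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0)
    stop2("zero cardiac amplitude in the blood reference region")
  q <- 100 * amp / ref
  out_mask <- mask %||% card_cycle$mask
  q[!out_mask] <- NA_real_
  quant_map(q, "perfusion_pct", out_mask)
}

#' Peak-to-trough amplitude of a reconstructed cycle, per voxel
#'
#' Computed over the full grid; used for the blood-region search.
#'
#' @param card_cycle a cycle from [reconstruct_cycle()].
#' @return numeric matrix of amplitudes.
#' @export
cycle_amplitude_map <- function(card_cycle) {
  v <- card_cycle$values
  r <- cycle_range(v)
  r$max - r$min
}

# vectorized per-voxel min/max over the bin dimension
cycle_range <- function(v) {
  d <- dim(v)
  mn <- matrix(v[, , 1], d[1], d[2])
  mx <- mn
  for (b in seq_len(d[3])[-1]) {
    mn <- pmin(mn, matrix(v[, , b], d[1], d[2]))
    mx <- pmax(mx, matrix(v[, , b], d[1], d[2]))
  }
  list(min = mn, max = mx)
}

#' Healthy reference region for the flow-volume-loop correlation
#'
#' The largest 4-connected region among voxels whose regional ventilation
#' lies within the 80th-90th percentile band of the in-mask distribution
#' (linear-interpolation percentiles). Ties between equally large components
#' are broken by the earliest label in deterministic raster order.
#'
#' @param vent_map a ventilation [quant_map()].
#' @param mask logical matrix (defaults to the map's mask).
#' @return logical matrix.
#' @export
healthy_reference_region <- function(vent_map, mask = NULL) {
  mask <- mask %||% vent_map$mask
  vals <- vent_map$values
  valid <- mask & !is.na(vals)
  if (sum(valid) < 10L) stop2("too few valid lung voxels (< 10)")
  p <- quantile(vals[valid], c(0.80, 0.90), type = 7, names = FALSE)
  sel <- valid & vals >= p[1] & vals <= p[2]
  if (!any(sel)) stop2("empty ventilation percentile band")
  lab <- label_components(sel)
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))[1] # earliest label on ties
  lab == best
}

#' Flow-volume-loop correlation map
#'
#' Per voxel, the reconstructed respiratory cycle is taken as a volume proxy
#' `V(b)` (normalized per voxel to `[0, 1]`); the flow curve is its circular
#' central difference `F(b) = (V(b+1) - V(b-1)) / 2` across phase bins. The
#' map value is the Pearson correlation between the voxel's flow curve and
#' the mean flow curve of the healthy reference region, evaluated at matched
#' phase bins. Voxels with zero flow variance carry the no-data marker.
#'
#' @param resp_cycle a `phase_cycle` over the respiratory phase.
#' @param reference_region logical matrix, non-empty.
#' @return a [quant_map()] of kind `"fvl_correlation"`.
#' @export
compute_fvl_correlation_map <- function(resp_cycle, reference_region) {
  if (!any(reference_region)) stop2("empty reference region")
  d <- dim(resp_cycle$values)
  nb <- resp_cycle$n_bins
  flat <- matrix(resp_cycle$values, d[1] * d[2], nb)
  idx <- which(resp_cycle$mask)
  v <- flat[idx, , drop = FALSE]
  rng <- apply(v, 1, max) - apply(v, 1, min)
  vn <- (v - apply(v, 1, min)) / ifelse(rng > 0, rng, NA_real_)
  nxt <- c(2:nb, 1); prv <- c(nb, 1:(nb - 1))
  flow <- (vn[, nxt, drop = FALSE] - vn[, prv, drop = FALSE]) / 2
  ref_rows <- which(resp_cycle$mask & reference_region)
  ref_flow <- colMeans(flow[match(ref_rows, idx), , drop = FALSE],
                       na.rm = TRUE)
  if (sd(ref_flow) == 0) stop2("reference region has zero flow variance")
  fsd <- apply(flow, 1, sd)
  r <- rep(NA_real_, length(idx))
  ok <- is.finite(fsd) & fsd > 0
  if (any(ok)) {
    fc <- flow[ok, , drop = FALSE] - rowMeans(flow[ok, , drop = FALSE])
    rc <- ref_flow - mean(ref_flow)
    r[ok] <- as.numeric(fc %*% rc) /
      (sqrt(rowSums(fc^2)) * sqrt(sum(rc^2)))
  }
  out <- matrix(NA_real_, d[1], d[2])
  out[idx] <- pmin(pmax(r, -1), 1)
  quant_map(out, "fvl_correlation", resp_cycle$mask)
}
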