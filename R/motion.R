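# Respiratory signal extraction, mid-expiration reference selection and
# nonrigid registration of the dynamic series.

#' Coarse thoracic mask from the temporal mean
#'
#' Body mask by Otsu thresholding of the temporal-mean image, minus the
#' high-intensity core (a second Otsu split inside the body), leaving the
#' low-signal parenchymal region that carries the respiratory modulation.
#' This breaks the segmentation/registration circularity: the proper lung
#' segmentation runs after registration.
#'
#' @param series an [image_series()].
#' @return logical matrix.
#' @export
coarse_lung_mask <- function(series) {
  m <- apply(series$frames, c(1, 2), mean)
  rng <- range(m)
  if (diff(rng) <= 0) stop2("uniform image: no body/lung contrast")
  mn <- (m - rng[1]) / diff(rng)
  body <- mn > EBImage::otsu(mn, range = c(0, 1))
  body <- EBImage::fillHull(body)
  inner <- mn[body]
  thr2 <- EBImage::otsu(matrix(inner, ncol = 1), range = c(0, 1))
  coarse <- body & (mn < thr2)
  coarse <- EBImage::opening(coarse, EBImage::makeBrush(3, "box")) > 0
  if (!any(coarse)) stop2("coarse mask empty: no low-intensity region inside the body")
  coarse
}

#' Mean signal inside a mask, per frame
#'
#' @param series an [image_series()].
#' @param coarse_mask logical matrix, non-empty.
#' @return numeric vector, one value per frame.
#' @export
global_lung_signal <- function(series, coarse_mask) {
  stopifnot(all(dim(coarse_mask) == grid_shape(series)))
  if (!any(coarse_mask)) stop2("empty mask")
  idx <- which(coarse_mask)
  nt <- n_frames(series)
  d <- dim(series$frames)
  flat <- matrix(series$frames, d[1] * d[2], d[3])
  colMeans(flat[idx, , drop = FALSE])
}

# Forward-backward filtering with reflected end-padding to suppress edge
# transients; zero-lag by construction.
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1L):(pad + n)]
}

#' Zero-lag Butterworth low-pass of a 1-D signal
#'
#' Order-4 Butterworth applied forward and backward (zero phase shift) with
#' reflected end-padding to suppress edge transients.
#'
#' @param x numeric vector.
#' @param cutoff_hz cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return filtered vector of the same length.
#' @export
lowpass_zero_lag <- function(x, cutoff_hz, fs) {
  wn <- min(cutoff_hz / (fs / 2), 0.95)
  bf <- signal::butter(4, wn, type = "low")
  filtfilt_padded(bf, x, pad = ceiling(2 * fs / cutoff_hz))
}

#' Extract the respiratory signal and per-frame respiratory phase
#'
#' The mask-mean signal is low-pass filtered with a zero-lag (forward-
#' backward Butterworth) filter; end-expiration peaks (signal maxima, since
#' inspiration dilutes proton density) and end-inspiration troughs are
#' detected with a minimum separation of half the estimated respiratory
#' period; respiratory phase is assigned by linear time interpolation
#' between consecutive end-expiration peaks (0 at each peak, < 1 before the
#' next). Frames before the first or after the last peak carry `NA` phase
#' and are excluded from cycle reconstruction.
#'
#' @param series an [image_series()].
#' @param coarse_mask logical matrix.
#' @param cutoff_hz low-pass cutoff, Hz (default 0.5; must lie below the
#'   cardiac band).
#' @return object of class `resp_signal` with elements `raw`, `smoothed`,
#'   `peaks`, `troughs`, `phase`, `times`, `resp_freq_hz`.
#' @export
extract_respiratory_signal <- function(series, coarse_mask,
                                       cutoff_hz = 0.5) {
  stopifnot(cutoff_hz > 0)
  fs <- 1 / series$frame_interval_s
  raw <- global_lung_signal(series, coarse_mask)
  sm <- lowpass_zero_lag(raw, cutoff_hz, fs)
  nt <- length(sm)
  # dominant respiratory frequency below the cutoff (excluding DC)
  sp <- Mod(fft(sm - mean(sm)))[seq_len(floor(nt / 2))]
  freqs <- (seq_len(floor(nt / 2)) - 1) * fs / nt
  band <- freqs > 0 & freqs <= cutoff_hz
  if (!any(band) || max(sp[band]) <= 0)
    stop2("series too short or motionless: no respiratory component")
  f_est <- freqs[band][which.max(sp[band])]
  if (f_est <= 0) stop2("series too short or motionless")
  min_sep <- max(2L, floor(0.5 / f_est * fs))
  pk <- pracma::findpeaks(sm, minpeakdistance = min_sep)
  tr <- pracma::findpeaks(-sm, minpeakdistance = min_sep)
  peaks <- if (is.null(pk)) integer(0) else sort(pk[, 2])
  troughs <- if (is.null(tr)) integer(0) else sort(tr[, 2])
  # discard spurious extrema: amplitude must be a reasonable fraction of the
  # (robust) overall modulation
  q <- quantile(sm, c(0.05, 0.95), type = 7, names = FALSE)
  amp <- diff(q)
  if (length(peaks))
    peaks <- peaks[sm[peaks] > q[1] + 0.4 * amp]
  if (length(troughs))
    troughs <- troughs[sm[troughs] < q[2] - 0.4 * amp]
  if (length(peaks) < 2L)
    stop2("fewer than 2 breaths detected: series too short or motionless")
  phase <- rep(NA_real_, nt)
  for (k in seq_len(length(peaks) - 1L)) {
    i0 <- peaks[k]; i1 <- peaks[k + 1L]
    idx <- i0:(i1 - 1L)
    phase[idx] <- (idx - i0) / (i1 - i0)
  }
  phase[peaks[length(peaks)]] <- 0
  structure(list(raw = raw, smoothed = sm, peaks = peaks, troughs = troughs,
                 phase = phase,
                 times = (seq_len(nt) - 1) * series$frame_interval_s,
                 resp_freq_hz = f_est),
            class = "resp_signal")
}

#' Select the mid-expiration reference frame
#'
#' The registration target is the frame whose smoothed respiratory signal is
#' closest to the midpoint between the median end-expiration peak level and
#' the median end-inspiration trough level, searched on the limbs descending
#' from each detected peak towards the following trough; ties are broken by
#' the earliest frame.
#'
#' @param resp a `resp_signal` from [extract_respiratory_signal()].
#' @return integer frame index.
#' @export
select_mid_expiration_frame <- function(resp) {
  stopifnot(inherits(resp, "resp_signal"))
  if (length(resp$peaks) < 1L)
    stop2("no full breath present")
  trough_level <- if (length(resp$troughs))
    median(resp$smoothed[resp$troughs]) else min(resp$smoothed)
  mid <- (median(resp$smoothed[resp$peaks]) + trough_level) / 2
  candidates <- integer(0)
  for (p in resp$peaks) {
    nxt <- resp$troughs[resp$troughs > p]
    end <- if (length(nxt)) min(nxt) else length(resp$smoothed)
    if (end > p + 1L) candidates <- c(candidates, (p + 1L):(end - 1L))
  }
  if (length(candidates) == 0L) stop2("no frames on descending limbs")
  d <- abs(resp$smoothed[candidates] - mid)
  candidates[which(d == min(d))[1]] # earliest on ties (candidates ascend)
}

# ---- Horn-Schunck optical flow registration ---------------------------------

#' Voxel-wise zero-phase temporal filtering of a frame array
#'
#' Filters every voxel's time course in the frequency domain with a
#' Butterworth magnitude response (zero phase by construction): low-pass,
#' high-pass or band-pass depending on which cutoffs are given. Low-pass
#' (via [temporal_lowpass_array()]) suppresses cardiac pulsation before
#' motion estimation; band-pass isolates the cardiac component for perfusion
#' mapping.
#'
#' @param frames numeric `X x Y x T` array.
#' @param fs sampling rate in Hz.
#' @param low_hz,high_hz band edges in Hz (`NULL` disables that edge).
#' @param order filter order (roll-off steepness).
#' @return filtered array with the same dimensions.
#' @export
temporal_filter_array <- function(frames, fs, low_hz = NULL, high_hz = NULL,
                                  order = 4) {
  d <- dim(frames)
  nt <- d[3]
  f <- c(0, seq_len(nt - 1)) * fs / nt
  f <- pmin(f, fs - f) # two-sided frequency axis
  h <- rep(1, nt)
  if (!is.null(high_hz)) h <- h / (1 + (f / high_hz)^(2 * order))
  if (!is.null(low_hz)) h <- h / (1 + (low_hz / pmax(f, 1e-12))^(2 * order))
  flat <- t(matrix(frames, d[1] * d[2], nt)) # nt x nvox
  X <- stats::mvfft(flat) * h
  sm <- Re(stats::mvfft(X, inverse = TRUE)) / nt
  array(t(sm), d)
}

#' @rdname temporal_filter_array
#' @param cutoff_hz low-pass cutoff in Hz.
#' @export
temporal_lowpass_array <- function(frames, cutoff_hz, fs, order = 4) {
  temporal_filter_array(frames, fs, high_hz = cutoff_hz, order = order)
}

hs_neighbor_avg <- function(m) {
  (shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
     shift_mat(m, 0, 1) + shift_mat(m, 0, -1)) / 6 +
    (shift_mat(m, 1, 1) + shift_mat(m, 1, -1) +
       shift_mat(m, -1, 1) + shift_mat(m, -1, -1)) / 12
}

grad_central <- function(m) {
  gi <- (shift_mat(m, -1, 0) - shift_mat(m, 1, 0)) / 2
  gj <- (shift_mat(m, 0, -1) - shift_mat(m, 0, 1)) / 2
  list(gi = gi, gj = gj)
}

downsample2 <- function(m) {
  n1 <- floor(nrow(m) / 2) * 2; n2 <- floor(ncol(m) / 2) * 2
  m <- m[seq_len(n1), seq_len(n2)]
  (m[seq(1, n1, 2), seq(1, n2, 2)] + m[seq(2, n1, 2), seq(1, n2, 2)] +
     m[seq(1, n1, 2), seq(2, n2, 2)] + m[seq(2, n1, 2), seq(2, n2, 2)]) / 4
}

upsample2_to <- function(m, shape) {
  # bilinear upsample of a flow component to `shape`
  src_i <- (seq_len(shape[1]) - 0.5) * nrow(m) / shape[1] + 0.5
  src_j <- (seq_len(shape[2]) - 0.5) * ncol(m) / shape[2] + 0.5
  sample_bilinear(m, matrix(src_i, shape[1], shape[2]),
                  matrix(src_j, shape[1], shape[2], byrow = TRUE))
}

# One Horn-Schunck solve at a single resolution, warm-started from (u, v);
# the Jacobi inner loop runs in compiled code (src/hs.cpp) and stops early
# once the largest per-voxel flow update drops below `tol` pixels.
hs_refine <- function(ref, mov, u, v, alpha, n_iter, n_warp, tol = 1e-3) {
  for (w in seq_len(n_warp)) {
    mov_w <- warp_bilinear(mov, u, v)
    g <- grad_central((mov_w + ref) / 2)
    it <- mov_w - ref
    d <- .hs_iterate(g$gi, g$gj, it, alpha, as.integer(n_iter), tol)
    u <- u + d$du; v <- v + d$dv
  }
  list(u = u, v = v)
}

# Multi-resolution Horn-Schunck flow: displacement (u, v) such that
# mov(x + u) ~= ref(x). `init` optionally warm-starts from a full-resolution
# flow (e.g. the previous frame of a smooth sequence).
hs_flow <- function(ref, mov, alpha = 2, n_iter = 120L, n_levels = 3L,
                    n_warp = 2L, init = NULL) {
  pyr_ref <- list(ref); pyr_mov <- list(mov)
  for (l in seq_len(n_levels - 1L)) {
    pyr_ref[[l + 1L]] <- downsample2(pyr_ref[[l]])
    pyr_mov[[l + 1L]] <- downsample2(pyr_mov[[l]])
  }
  if (is.null(init)) {
    u <- v <- matrix(0, nrow(pyr_ref[[n_levels]]), ncol(pyr_ref[[n_levels]]))
  } else {
    u <- init$u; v <- init$v
    for (l in seq_len(n_levels - 1L)) {
      u <- downsample2(u) / 2; v <- downsample2(v) / 2
    }
  }
  for (l in rev(seq_len(n_levels))) {
    res <- hs_refine(pyr_ref[[l]], pyr_mov[[l]], u, v, alpha,
                     n_iter, n_warp)
    u <- res$u; v <- res$v
    if (l > 1L) {
      shape <- dim(pyr_ref[[l - 1L]])
      u <- upsample2_to(u, shape) * (shape[1] / nrow(res$u))
      v <- upsample2_to(v, shape) * (shape[2] / ncol(res$v))
    }
  }
  list(u = u, v = v)
}

#' Register all frames to a reference frame
#'
#' 2D nonrigid registration by multi-resolution Horn-Schunck optical flow
#' (quadratic smoothness penalty); each frame is warped to the reference
#' geometry with bilinear intensity interpolation. Masks should be warped
#' with [warp_mask_to_frame()] (nearest-neighbour).
#'
#' @param series an [image_series()].
#' @param reference_frame_index integer in `1..n_frames`.
#' @param settings list with `alpha` (smoothness weight), `n_iter`
#'   (iterations per warp), `n_levels` (pyramid levels), `n_warp` (warp
#'   updates per level).
#' @return object of class `registered_series`: `frames` (warped array),
#'   `reference_frame_index`, `flow` (list of per-frame `u`/`v` fields,
#'   frame coordinates relative to the reference), `mean_displacement_px`
#'   per frame, plus the series metadata.
#' @export
register_series <- function(series, reference_frame_index,
                            settings = list(alpha = 2, n_iter = 120L,
                                            n_levels = 3L, n_warp = 2L)) {
  nt <- n_frames(series)
  if (reference_frame_index < 1L || reference_frame_index > nt)
    stop2("reference frame index out of range")
  # motion is estimated on cardiac-suppressed frames (temporal low-pass) so
  # the flow tracks respiration, not blood inflow; the original frames are
  # then warped with that flow
  cutoff <- settings$motion_lowpass_hz %||% 0.6
  fs <- 1 / series$frame_interval_s
  est <- if (is.finite(cutoff) && cutoff > 0 && cutoff < fs / 2)
    temporal_lowpass_array(series$frames, cutoff, fs)
  else series$frames
  ref <- est[, , reference_frame_index]
  sc <- max(abs(ref), 1e-12) # intensity scale so alpha is scale-free
  out <- array(0, dim(series$frames))
  flow <- vector("list", nt)
  mean_disp <- numeric(nt)
  zero <- matrix(0, nrow(ref), ncol(ref))
  out[, , reference_frame_index] <- series$frames[, , reference_frame_index]
  flow[[reference_frame_index]] <- list(u = zero, v = zero)
  # frames are processed outward from the reference; each is warm-started
  # from its already-solved temporal neighbour (the estimation frames are
  # cardiac-suppressed, so the flow varies smoothly in time)
  order_k <- c(rev(seq_len(reference_frame_index - 1L)),
               seq(reference_frame_index + 1L, length.out =
                     nt - reference_frame_index))
  for (k in order_k) {
    prev <- if (k < reference_frame_index) k + 1L else k - 1L
    f <- hs_flow(ref / sc, est[, , k] / sc,
                 alpha = settings$alpha %||% 2,
                 n_iter = settings$n_iter %||% 120L,
                 n_levels = settings$n_levels %||% 3L,
                 n_warp = settings$n_warp %||% 2L,
                 init = flow[[prev]])
    out[, , k] <- warp_bilinear(series$frames[, , k], f$u, f$v)
    flow[[k]] <- f
    mean_disp[k] <- mean(sqrt(f$u^2 + f$v^2))
  }
  structure(list(frames = out,
                 reference_frame_index = as.integer(reference_frame_index),
                 flow = flow, mean_displacement_px = mean_disp,
                 pixel_spacing_mm = series$pixel_spacing_mm,
                 frame_interval_s = series$frame_interval_s,
                 identifier = series$identifier),
            class = "registered_series")
}

#' @rdname register_series
#' @param registered a `registered_series`.
#' @param mask logical matrix in a source frame's geometry.
#' @param frame_index which frame's geometry the mask lives in.
#' @export
warp_mask_to_frame <- function(registered, mask, frame_index) {
  f <- registered$flow[[frame_index]]
  warp_nearest(mask, f$u, f$v)
}

#' Residual displacement against a known motion field
#'
#' Compares the estimated flow of a [register_series()] result with a known
#' per-voxel vertical displacement field (such as the phantom motion truth,
#' expressed relative to the neutral end-expiration position). The truth is
#' first re-expressed relative to the reference frame; the residual for each
#' frame is the mean flow-vector error magnitude over `mask`.
#'
#' @param registered a `registered_series`.
#' @param true_displacement numeric `X x Y x T` array of true downward
#'   (column-direction) displacement in pixels, relative to the neutral
#'   position, or `NULL` for a motionless ground truth.
#' @param mask optional logical matrix restricting the evaluation region.
#' @return numeric vector of per-frame mean residuals in pixels.
#' @export
residual_displacement <- function(registered, true_displacement = NULL,
                                  mask = NULL) {
  nt <- length(registered$flow)
  dm <- dim(registered$frames)[1:2]
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  ref <- registered$reference_frame_index
  d_ref <- if (is.null(true_displacement)) 0 else true_displacement[, , ref]
  vapply(seq_len(nt), function(k) {
    f <- registered$flow[[k]]
    v_true <- if (is.null(true_displacement)) 0 else
      true_displacement[, , k] - d_ref
    err <- sqrt(f$u^2 + (f$v - v_true)^2)
    mean(err[mask])
  }, numeric(1))
}
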