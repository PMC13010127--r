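# Lung parenchyma segmentation (classical intensity + morphology baseline)
# and localization of the full-blood reference region between the lungs.

#' Segment the lung parenchyma on a registered series
#'
#' Classical baseline: on the temporal-mean image, take low-intensity
#' regions inside the (hole-filled) body mask, clean them morphologically,
#' and keep the two largest connected components. Deterministic. A
#' user-supplied mask bypasses the baseline entirely (it is validated for
#' geometry and used as-is).
#'
#' @param registered a `registered_series` (an [image_series()] is also
#'   accepted).
#' @param user_mask optional logical matrix; if given, validated and
#'   returned.
#' @param min_area minimum component area in voxels (default 25).
#' @return object of class `lung_mask`: `mask` (logical), `labels` (integer
#'   matrix, 1 = left/lower-x component, 2 = right), `area_voxels`,
#'   `area_mm2`.
#' @export
segment_lungs <- function(registered, user_mask = NULL, min_area = 25L) {
  shape <- dim(registered$frames)[1:2]
  spacing <- registered$pixel_spacing_mm %||% c(1, 1)
  if (!is.null(user_mask)) {
    if (!all(dim(user_mask) == shape))
      stop2("user mask geometry does not match the series")
    return(as_lung_mask(user_mask == TRUE, spacing))
  }
  m <- apply(registered$frames, c(1, 2), mean)
  rng <- range(m)
  if (diff(rng) <= 0) stop2("no lung candidate: uniform image")
  mn <- (m - rng[1]) / diff(rng)
  body <- EBImage::fillHull(mn > EBImage::otsu(mn, range = c(0, 1)))
  inner <- mn[body]
  thr2 <- EBImage::otsu(matrix(inner, ncol = 1), range = c(0, 1))
  cand <- body & (mn < thr2)
  cand <- EBImage::opening(cand, EBImage::makeBrush(5, "disc")) > 0
  cand <- EBImage::fillHull(cand)
  mask <- keep_largest_components(cand, k = 2L, min_area = min_area)
  if (!any(mask)) stop2("no lung candidate found")
  as_lung_mask(mask, spacing)
}

as_lung_mask <- function(mask, spacing = c(1, 1)) {
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp > 2L) {
    # retain at most two components (largest)
    sizes <- tabulate(lab)
    keep <- order(sizes, decreasing = TRUE)[1:2]
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    lab <- label_components(mask)
    ncomp <- max(lab)
  }
  if (ncomp == 2L) {
    # relabel so component 1 has the smaller centroid column (left lung)
    cx <- vapply(1:2, function(l) mean(which(lab == l, arr.ind = TRUE)[, 1]),
                 0)
    if (cx[1] > cx[2]) lab[lab > 0L] <- 3L - lab[lab > 0L]
  }
  structure(list(mask = mask, labels = lab,
                 area_voxels = sum(mask),
                 area_mm2 = sum(mask) * prod(spacing)),
            class = "lung_mask")
}

# Inter-lung corridor: columns strictly between the two lung components'
# bounding hulls, over the rows the lungs span, excluding lung voxels.
interlung_corridor <- function(lung_mask) {
  lab <- lung_mask$labels
  if (max(lab) < 2L) stop2("corridor undefined: need two lung components")
  idx1 <- which(lab == 1L, arr.ind = TRUE)
  idx2 <- which(lab == 2L, arr.ind = TRUE)
  x_lo <- max(idx1[, 1]); x_hi <- min(idx2[, 1])
  if (x_hi - x_lo < 2L) stop2("empty inter-lung corridor")
  rows <- range(c(idx1[, 2], idx2[, 2]))
  corridor <- matrix(FALSE, nrow(lab), ncol(lab))
  corridor[(x_lo + 1L):(x_hi - 1L), rows[1]:rows[2]] <- TRUE
  corridor & !lung_mask$mask
}

#' Locate the full-blood reference region between the lungs
#'
#' Searches the inter-lung corridor (the columns strictly between the two
#' lung components' bounding hulls, over the rows the lungs span, excluding
#' lung voxels) for the connected region of highest mean cardiac amplitude
#' above an adaptive floor: the 75th percentile of corridor amplitudes,
#' guarded from below by 30% of the corridor maximum. Ties are broken by
#' larger area, then by smaller centroid column.
#'
#' @param perf_amplitude_map numeric matrix of cardiac-cycle peak-to-trough
#'   amplitudes (signal units), defined at least on the corridor.
#' @param lung_mask a `lung_mask` with two components.
#' @return logical matrix marking the reference region.
#' @export
find_full_blood_region <- function(perf_amplitude_map, lung_mask) {
  stopifnot(inherits(lung_mask, "lung_mask"))
  corridor <- interlung_corridor(lung_mask)
  amp <- perf_amplitude_map
  vals <- amp[corridor]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop2("no blood reference found: empty corridor")
  # 75th percentile of corridor amplitudes, with a relative guard at 30% of
  # the corridor maximum so a near-noiseless background cannot drag the
  # floor towards zero
  floor_amp <- max(quantile(vals, 0.75, type = 7, names = FALSE),
                   0.3 * max(vals))
  cand <- corridor & is.finite(amp) & (amp > floor_amp)
  if (!any(cand)) stop2("no blood reference found: no voxel above the amplitude floor")
  cl <- label_components(cand)
  ncomp <- max(cl)
  stats <- t(vapply(seq_len(ncomp), function(l) {
    sel <- cl == l
    c(mean_amp = mean(amp[sel]), area = sum(sel),
      cx = mean(which(sel, arr.ind = TRUE)[, 1]))
  }, c(0, 0, 0)))
  ord <- order(-stats[, "mean_amp"], -stats[, "area"], stats[, "cx"])
  best <- ord[1]
  region <- cl == best
  stopifnot(!any(region & lung_mask$mask))
  region
}
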