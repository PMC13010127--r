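# Defect thresholding of the quantitative maps, lung-level metrics and
# severity stratification.

#' Defect-threshold configuration
#'
#' Printed defaults from a large 1.5 T calibration cohort: perfusion defect
#' below 2% normalized perfusion; ventilation defect below 40% of the 90th
#' ventilation percentile; flow-volume-loop defect below a correlation of
#' 0.9. These were optimized at 1.5 T with a FLASH sequence; at other field
#' strengths they are a transferred convention, which every report records.
#'
#' @param perfusion_defect_threshold percent (default 2.0).
#' @param vent_defect_fraction unitless fraction of the 90th ventilation
#'   percentile (default 0.40).
#' @param fvl_defect_threshold correlation in (0, 1] (default 0.9).
#' @param vdp_mode `"regional_ventilation"` (headline) or `"fvl"`.
#' @return object of class `quantification_config`.
#' @export
quantification_config <- function(perfusion_defect_threshold = 2.0,
                                  vent_defect_fraction = 0.40,
                                  fvl_defect_threshold = 0.9,
                                  vdp_mode = c("regional_ventilation",
                                               "fvl")) {
  stopifnot(perfusion_defect_threshold > 0,
            vent_defect_fraction > 0, vent_defect_fraction < 1,
            fvl_defect_threshold > 0, fvl_defect_threshold <= 1)
  structure(list(perfusion_defect_threshold = perfusion_defect_threshold,
                 vent_defect_fraction = vent_defect_fraction,
                 fvl_defect_threshold = fvl_defect_threshold,
                 vdp_mode = match.arg(vdp_mode)),
            class = "quantification_config")
}

#' Classify voxels into defect categories
#'
#' A voxel is a ventilation defect iff its regional ventilation is strictly
#' below `vent_defect_fraction * P90(RV)` over the valid mask (or, in
#' `"fvl"` mode, iff its flow-volume-loop correlation is strictly below the
#' FVL threshold); a perfusion defect iff normalized perfusion is strictly
#' below the perfusion threshold. A value exactly at a threshold is
#' non-defect. Categories partition the valid lung exactly: defect in both
#' maps = V/Q defect; in exactly one = exclusive defect; in neither = V/Q
#' match. Voxels with no-data in any required map are excluded from all
#' denominators.
#'
#' @param vent_map,perf_map,fvl_map [quant_map()]s on the same grid
#'   (`fvl_map` may be `NULL` in regional-ventilation mode).
#' @param mask logical lung mask (or a `lung_mask`).
#' @param config a [quantification_config()].
#' @return object of class `defect_classification`: `category` (character
#'   matrix: vent_defect_only / perf_defect_only / vq_defect / vq_match /
#'   no_data, `NA` outside mask), per-category logical masks, `valid`
#'   (logical), and the realized `vent_threshold`.
#' @export
classify_defects <- function(vent_map, perf_map, fvl_map = NULL, mask,
                             config = quantification_config()) {
  if (inherits(mask, "lung_mask")) mask <- mask$mask
  stopifnot(all(dim(vent_map$values) == dim(mask)),
            all(dim(perf_map$values) == dim(mask)))
  use_fvl <- config$vdp_mode == "fvl"
  if (use_fvl && is.null(fvl_map))
    stop2("vdp_mode = 'fvl' requires an FVL correlation map")
  vent_vals <- vent_map$values
  valid <- mask & !is.na(vent_vals) & !is.na(perf_map$values)
  if (use_fvl) valid <- valid & !is.na(fvl_map$values)
  if (!any(valid)) stop2("no valid voxels in mask")
  p90 <- quantile(vent_vals[mask & !is.na(vent_vals)], 0.90, type = 7,
                  names = FALSE)
  vent_threshold <- config$vent_defect_fraction * p90
  vent_def <- if (use_fvl) {
    valid & fvl_map$values < config$fvl_defect_threshold
  } else {
    valid & vent_vals < vent_threshold
  }
  perf_def <- valid & perf_map$values < config$perfusion_defect_threshold
  cat_mat <- matrix(NA_character_, nrow(mask), ncol(mask))
  cat_mat[mask] <- "no_data"
  cat_mat[valid & vent_def & perf_def] <- "vq_defect"
  cat_mat[valid & vent_def & !perf_def] <- "vent_defect_only"
  cat_mat[valid & !vent_def & perf_def] <- "perf_defect_only"
  cat_mat[valid & !vent_def & !perf_def] <- "vq_match"
  structure(list(category = cat_mat,
                 vent_defect_only = valid & vent_def & !perf_def,
                 perf_defect_only = valid & !vent_def & perf_def,
                 vq_defect = valid & vent_def & perf_def,
                 vq_match = valid & !vent_def & !perf_def,
                 valid = valid, mask = mask,
                 vent_threshold = if (use_fvl) config$fvl_defect_threshold
                 else vent_threshold,
                 config = config),
            class = "defect_classification")
}

#' Lung-level metrics from a defect classification
#'
#' Percentages of the valid lung area per category plus mean ventilation and
#' perfusion. The partition identities hold exactly: VDP = exclusive
#' ventilation defect + V/Q defect; QDP = exclusive perfusion defect + V/Q
#' defect; the four categories sum to 100% (the non-defect share is defined
#' as the closure remainder of the other three).
#'
#' @param classification a `defect_classification`.
#' @param vent_map,perf_map the maps the classification was built from.
#' @param series_id,config_hash provenance strings recorded in the report.
#' @return object of class `metrics_report`.
#' @export
compute_metrics <- function(classification, vent_map, perf_map,
                            series_id = NA_character_,
                            config_hash = NA_character_) {
  valid <- classification$valid
  n_valid <- sum(valid)
  if (n_valid == 0L) stop2("empty valid mask")
  pct <- function(m) 100 * sum(m) / n_valid
  vo <- pct(classification$vent_defect_only)
  po <- pct(classification$perf_defect_only)
  vq <- pct(classification$vq_defect)
  # closure convention: the non-defect share is the remainder, so the four
  # category percentages sum to exactly 100 in floating point (the voxel
  # counts partition the valid area exactly; the rounded percentages alone
  # need not)
  nm <- 100 - (vo + po + vq)
  structure(list(
    mean_ventilation = mean(vent_map$values[valid]),
    mean_perfusion = mean(perf_map$values[valid]),
    vdp = vo + vq, qdp = po + vq,
    vqm_defect = vq, vqm_nondefect = nm,
    pct_vent_defect_only = vo, pct_perf_defect_only = po,
    area_valid_voxels = n_valid,
    area_no_data_voxels = sum(classification$mask) - n_valid,
    vent_threshold = classification$vent_threshold,
    perfusion_defect_threshold =
      classification$config$perfusion_defect_threshold,
    vdp_mode = classification$config$vdp_mode,
    threshold_provenance =
      "defect thresholds calibrated at 1.5 T (FLASH); configurable",
    series_id = series_id, config_hash = config_hash),
    class = "metrics_report")
}

#' Severity stratum from vital capacity
#'
#' Severity bins on VC in percent predicted: mild for VC >= 88 (including
#' supranormal values), moderate for 58 <= VC < 88, severe for VC < 58 —
#' the continuous closure of the printed integer bins 100-88 / 87-58 /
#' 57-0.
#'
#' @param vc_percent VC in percent predicted (vectorized, >= 0).
#' @return factor with levels mild, moderate, severe.
#' @export
stratify_by_vc <- function(vc_percent) {
  if (any(vc_percent < 0, na.rm = TRUE)) stop2("negative VC")
  out <- ifelse(vc_percent >= 88, "mild",
                ifelse(vc_percent >= 58, "moderate", "severe"))
  factor(out, levels = c("mild", "moderate", "severe"))
}
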