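# End-to-end orchestration: motion -> segmentation -> phase-resolved maps ->
# defect quantification, plus the command entry points used by the CLI
# script (inst/cli/preful.R).

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2(sprintf("stage '%s': %s", name, conditionMessage(e)))
  })
}

#' Run the full functional-lung analysis on a series
#'
#' Executes the whole pipeline in memory: coarse mask, respiratory signal,
#' mid-expiration reference, nonrigid registration, lung segmentation (or a
#' user-supplied mask), cardiac phase from an inter-lung seed, phase-sorted
#' respiratory and cardiac cycles, ventilation / perfusion /
#' flow-volume-loop maps, full-blood normalization, and defect
#' classification in both the regional-ventilation and FVL modes.
#'
#' @param series an [image_series()].
#' @param config a [run_config()].
#' @param user_mask optional logical lung mask (bypasses segmentation).
#' @return object of class `preful_result` holding the registered series,
#'   masks, respiratory/cardiac signals, maps, classifications and the
#'   primary `metrics_report` (field `report`; the FVL-mode variant is
#'   `report_fvl`), plus a run `log`.
#' @export
run_preful <- function(series, config = run_config(), user_mask = NULL) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  t0 <- Sys.time()
  note("input series '%s': %d x %d, %d frames @ %.3g s", series$identifier,
       grid_shape(series)[1], grid_shape(series)[2], n_frames(series),
       series$frame_interval_s)
  note("settings: n_bins=%d, resp lowpass %.2f Hz, cardiac band %.2f-%.2f Hz, vent fraction %.2f of P90, perfusion threshold %.2f%%, FVL threshold %.2f, registration alpha=%.2g iters=%d levels=%d",
       config$n_bins, config$resp_lowpass_hz, config$cardiac_band_hz[1],
       config$cardiac_band_hz[2], config$quant$vent_defect_fraction,
       config$quant$perfusion_defect_threshold,
       config$quant$fvl_defect_threshold,
       config$registration$alpha %||% 2, config$registration$n_iter %||% 120L,
       config$registration$n_levels %||% 3L)

  coarse <- stage("motion", coarse_lung_mask(series))
  resp <- stage("motion", extract_respiratory_signal(
    series, coarse, cutoff_hz = config$resp_lowpass_hz))
  note("respiratory frequency %.3f Hz, %d end-expiration peaks",
       resp$resp_freq_hz, length(resp$peaks))
  ref <- stage("motion", select_mid_expiration_frame(resp))
  note("mid-expiration reference frame: %d", ref)
  reg <- stage("motion", register_series(series, ref,
                                         settings = config$registration))
  lungs <- stage("segmentation", segment_lungs(reg, user_mask = user_mask))
  note("lung mask: %d voxels (%.0f mm^2), %d component(s)",
       lungs$area_voxels, lungs$area_mm2, max(lungs$labels))

  corridor <- stage("segmentation", interlung_corridor(lungs))
  tmean <- apply(reg$frames, c(1, 2), mean)
  seed0 <- corridor & tmean > median(tmean[corridor])
  if (!any(seed0)) seed0 <- corridor
  card <- stage("preful_core", extract_cardiac_phase(
    reg, seed0, band_hz = config$cardiac_band_hz))
  note("cardiac frequency %.3f Hz", card$frequency_hz)

  # the cardiac component is isolated voxel-wise (zero-phase band-pass)
  # before phase sorting, so the much larger respiratory modulation cannot
  # leak into the perfusion amplitude
  reg_card <- reg
  reg_card$frames <- temporal_filter_array(
    reg$frames, fs = 1 / series$frame_interval_s,
    low_hz = config$cardiac_band_hz[1],
    high_hz = min(config$cardiac_band_hz[2],
                  0.98 / (2 * series$frame_interval_s)))
  card_cycle <- stage("preful_core", reconstruct_cycle(
    reg_card, card$phase, lungs$mask | corridor, n_bins = config$n_bins))
  amp <- cycle_amplitude_map(card_cycle)
  blood <- stage("segmentation", find_full_blood_region(amp, lungs))
  note("full-blood region: %d voxels", sum(blood))
  # the map keeps the blood reference region so its 100% normalization
  # identity is visible in the output, not just internally
  perf_map <- stage("preful_core", compute_perfusion_map(
    card_cycle, blood, mask = lungs$mask | blood))

  resp_cycle <- stage("preful_core", reconstruct_cycle(
    reg, resp$phase, lungs$mask, n_bins = config$n_bins))
  mid_phase <- resp$phase[ref]
  if (is.na(mid_phase)) mid_phase <- 0.25 # reference fell outside the span
  mid_bin <- pmin(floor(mid_phase * config$n_bins), config$n_bins - 1L) + 1L
  note("mid-expiration phase %.3f -> bin %d of %d", mid_phase, mid_bin,
       config$n_bins)
  vent_map <- stage("preful_core", compute_ventilation_map(resp_cycle,
                                                           mid_bin))
  healthy <- stage("preful_core", healthy_reference_region(vent_map))
  fvl_map <- stage("preful_core", compute_fvl_correlation_map(resp_cycle,
                                                              healthy))

  cls <- stage("quantification", classify_defects(
    vent_map, perf_map, fvl_map, lungs, config$quant))
  chash <- config_hash(config)
  report <- stage("quantification", compute_metrics(
    cls, vent_map, perf_map, series_id = series$identifier,
    config_hash = chash))
  cfg_fvl <- config$quant; cfg_fvl$vdp_mode <- "fvl"
  cls_fvl <- stage("quantification", classify_defects(
    vent_map, perf_map, fvl_map, lungs, cfg_fvl))
  report_fvl <- stage("quantification", compute_metrics(
    cls_fvl, vent_map, perf_map, series_id = series$identifier,
    config_hash = chash))
  note("V %.2f%%  Q %.2f%%  VDP %.2f%%  QDP %.2f%%  VQM defect %.2f%%  VQM non-defect %.2f%%",
       report$mean_ventilation, report$mean_perfusion, report$vdp,
       report$qdp, report$vqm_defect, report$vqm_nondefect)
  note("elapsed %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(registered = reg, resp = resp, cardiac = card,
                 reference_frame = ref, lungs = lungs, blood = blood,
                 healthy_region = healthy,
                 resp_cycle = resp_cycle, card_cycle = card_cycle,
                 vent_map = vent_map, perf_map = perf_map,
                 fvl_map = fvl_map,
                 classification = cls, classification_fvl = cls_fvl,
                 report = report, report_fvl = report_fvl,
                 config = config, config_hash = chash, log = log),
            class = "preful_result")
}

category_codes <- c(vq_match = 0L, vent_defect_only = 1L,
                    perf_defect_only = 2L, vq_defect = 3L, no_data = 4L)

# grayscale [0,1] matrix -> PNG (written via the png package, headless-safe)
write_png_gray <- function(m, path) {
  m[!is.finite(m)] <- 0
  rng <- range(m)
  if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
  png::writePNG(t(m), path) # transpose so x is horizontal
  invisible(path)
}

#' Simulate a phantom and write it to disk
#'
#' Writes the dynamic series as NIfTI (X x Y x 1 x T), the true lung /
#' blood / defect masks, the analytic truth maps, and a JSON sidecar with
#' the full phantom specification and file inventory.
#'
#' @param spec a [phantom_spec()] or the path to a YAML file of its fields.
#' @param out_dir output directory (created).
#' @return invisibly, the list of written paths.
#' @export
cmd_simulate <- function(spec, out_dir) {
  if (is.character(spec)) {
    y <- yaml::read_yaml(spec)
    if (!is.null(y$grid_shape)) y$grid_shape <- unlist(y$grid_shape)
    if (!is.null(y$baseline_signal))
      y$baseline_signal <- as.list(y$baseline_signal)
    spec <- do.call(phantom_spec, y)
  }
  stopifnot(inherits(spec, "phantom_spec"))
  ph <- generate_phantom(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_series(ph$series, p("series.nii.gz"))
  sp <- spec$pixel_spacing_mm
  write_mask(ph$truth$lung_mask, p("lung_mask.nii.gz"), sp)
  write_mask(ph$truth$blood_region_mask, p("blood_mask.nii.gz"), sp)
  write_mask(ph$truth$vent_defect_mask, p("vent_defect_mask.nii.gz"), sp)
  write_mask(ph$truth$perf_defect_mask, p("perf_defect_mask.nii.gz"), sp)
  tv <- ph$truth$true_ventilation_map
  write_map(quant_map(tv, "ventilation_pct", ph$truth$lung_mask),
            p("true_ventilation.nii.gz"), sp)
  sidecar <- list(
    spec = unclass(spec),
    files = list(series = "series.nii.gz", lung_mask = "lung_mask.nii.gz",
                 blood_mask = "blood_mask.nii.gz",
                 vent_defect_mask = "vent_defect_mask.nii.gz",
                 perf_defect_mask = "perf_defect_mask.nii.gz",
                 true_ventilation = "true_ventilation.nii.gz"),
    vent_defect_fraction = ph$truth$vent_defect_fraction,
    perf_defect_fraction = ph$truth$perf_defect_fraction,
    resp_phase = ph$truth$resp_phase,
    cardiac_phase = ph$truth$cardiac_phase)
  jsonlite::write_json(sidecar, p("phantom.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(lapply(sidecar$files, function(f) p(f)))
}

#' Run the pipeline on a series file and write all artifacts
#'
#' @param series_path NIfTI (or DICOM directory) path.
#' @param out_dir output directory (created).
#' @param config_path optional YAML [run_config()]; defaults used otherwise.
#' @param mask_path optional NIfTI lung mask (bypasses segmentation).
#' @param frame_interval_s explicit temporal-resolution override.
#' @param format `"nifti"` or `"dicom_dir"`.
#' @param vdp_mode override the headline VDP mode.
#' @return invisibly, the `preful_result`.
#' @export
cmd_run <- function(series_path, out_dir, config_path = NULL,
                    mask_path = NULL, frame_interval_s = NULL,
                    format = c("nifti", "dicom_dir"), vdp_mode = NULL) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed <- function(stage_msg) {
    writeLines(stage_msg, file.path(out_dir, "FAILED"))
  }
  config <- if (!is.null(config_path)) read_run_config(config_path)
  else run_config()
  if (!is.null(vdp_mode))
    config$quant$vdp_mode <- match.arg(vdp_mode,
                                       c("regional_ventilation", "fvl"))
  res <- tryCatch({
    series <- stage("io", read_series(series_path, format = format,
                                      frame_interval_s = frame_interval_s))
    user_mask <- if (!is.null(mask_path))
      stage("io", read_mask(mask_path)) else NULL
    run_preful(series, config = config, user_mask = user_mask)
  }, error = function(e) {
    failed(conditionMessage(e))
    stop2(conditionMessage(e))
  })
  p <- function(f) file.path(out_dir, f)
  sp <- res$registered$pixel_spacing_mm
  write_map(res$vent_map, p("ventilation.nii.gz"), sp)
  write_map(res$perf_map, p("perfusion.nii.gz"), sp)
  write_map(res$fvl_map, p("fvl_correlation.nii.gz"), sp)
  write_mask(res$lungs$mask, p("lung_mask.nii.gz"), sp)
  write_mask(res$blood, p("blood_mask.nii.gz"), sp)
  labels <- matrix(category_codes["no_data"], nrow(res$lungs$mask),
                   ncol(res$lungs$mask))
  for (nm in names(category_codes))
    if (!is.null(res$classification[[nm]]))
      labels[res$classification[[nm]]] <- category_codes[[nm]]
  labels[!res$lungs$mask] <- 255L
  img <- RNifti::asNifti(array(as.integer(labels), c(dim(labels), 1L)))
  RNifti::writeNifti(img, p("defect_categories.nii.gz"), datatype = "uint8")
  write_report(res$report, p("report.json"), p("report.csv"))
  write_report(res$report_fvl, p("report_fvl.json"), NULL)
  qc <- data.frame(frame = seq_along(res$resp$raw), raw = res$resp$raw,
                   smoothed = res$resp$smoothed,
                   resp_phase = res$resp$phase,
                   cardiac_phase = res$cardiac$phase)
  write.csv(qc, p("respiratory_signal.csv"), row.names = FALSE)
  write_run_config(res$config, p("config.yaml"))
  # QC panels: temporal mean with masks, and the three maps
  tm <- apply(res$registered$frames, c(1, 2), mean)
  ov <- (tm - min(tm)) / diff(range(tm))
  rgb <- array(rep(t(ov), 3), c(ncol(ov), nrow(ov), 3))
  rgb[, , 1][t(res$lungs$mask)] <- 1
  rgb[, , 3][t(res$blood)] <- 1
  try(png::writePNG(rgb, p("qc_masks.png")), silent = TRUE)
  try(write_png_gray(res$vent_map$values, p("qc_ventilation.png")),
      silent = TRUE)
  try(write_png_gray(res$perf_map$values, p("qc_perfusion.png")),
      silent = TRUE)
  try(write_png_gray(labels, p("qc_defects.png")), silent = TRUE)
  writeLines(res$log, p("run.log"))
  invisible(res)
}

#' Run the cohort statistics layer on a subject table
#'
#' Writes HV-vs-patient comparisons per metric (normality-gated test),
#' severity- and NIV-stratified summaries with one-way ANOVA across strata,
#' and the Spearman correlation matrix of all numeric columns.
#'
#' @param csv_path subject table (see [read_subject_table()]).
#' @param out_dir output directory (created).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return invisibly, a list of the computed tables.
#' @export
cmd_stats <- function(csv_path, out_dir, alpha_normality = 0.05) {
  records <- stage("io", read_subject_table(csv_path))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  num <- names(records)[vapply(records, is.numeric, TRUE)]
  comparisons <- stage("cohort_stats", compare_groups_table(
    records, metrics = num, alpha_normality = alpha_normality))
  write.csv(comparisons, p("comparisons.csv"), row.names = FALSE)
  out <- list(comparisons = comparisons)
  if ("vc_percent" %in% names(records)) {
    sev <- subgroup_summary(records, "severity")
    write.csv(sev, p("severity_summary.csv"), row.names = FALSE)
    out$severity <- sev
    metrics_sev <- setdiff(num, c("vc_percent", "fvc_percent",
                                  "fev1_percent", "pef_percent"))
    strat <- ifelse(records$group == "HV", "HV",
                    as.character(stratify_by_vc(records$vc_percent)))
    anovas <- lapply(metrics_sev, function(mt) {
      groups <- split(records[[mt]], strat)
      groups <- groups[vapply(groups, function(g)
        sum(is.finite(g)) >= 2L, TRUE)]
      if (length(groups) < 3L) return(NULL)
      a <- anova_oneway(groups, metric = mt)
      data.frame(metric = mt, F = a$statistic, df1 = a$df[1],
                 df2 = a$df[2], p_value = a$p_value)
    })
    anovas <- do.call(rbind, anovas)
    if (!is.null(anovas))
      write.csv(anovas, p("severity_anova.csv"), row.names = FALSE)
    out$severity_anova <- anovas
  }
  if ("niv" %in% names(records)) {
    niv <- subgroup_summary(records, "niv")
    write.csv(niv, p("niv_summary.csv"), row.names = FALSE)
    out$niv <- niv
  }
  rs <- spearman_matrix(records[num])
  jsonlite::write_json(list(variables = colnames(rs),
                            rs = as.data.frame(rs)),
                       p("spearman.json"), digits = NA, pretty = TRUE,
                       na = "null")
  out$spearman <- rs
  invisible(out)
}

#' Command-line dispatcher
#'
#' Implements the `simulate`, `run` and `stats` commands used by the
#' `inst/cli/preful.R` script. Exit codes: 0 success, 2 input error,
#' 3 stage failure.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status.
#' @export
preful_main <- function(args) {
  usage <- paste(
    "usage: preful.R <command> [options]",
    "commands:",
    "  simulate --out DIR [--spec FILE.yaml] [--seed N]",
    "  run SERIES --out DIR [--config FILE.yaml] [--mask FILE.nii]",
    "             [--frame-interval S] [--vdp-mode rv|fvl] [--dicom]",
    "  stats TABLE.csv --out DIR", sep = "\n")
  if (length(args) < 1L) { message(usage); return(2L) }
  cmd <- args[1]; args <- args[-1]
  opt <- list(); pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opt[[key]] <- TRUE; i <- i + 1L
      } else { opt[[key]] <- args[i + 1L]; i <- i + 2L }
    } else { pos <- c(pos, a); i <- i + 1L }
  }
  if (is.null(opt$out)) { message("--out is required\n", usage); return(2L) }
  res <- tryCatch({
    if (cmd == "simulate") {
      spec <- if (!is.null(opt$spec)) opt$spec
      else phantom_spec(seed = as.integer(opt$seed %||% 1L))
      cmd_simulate(spec, opt$out)
    } else if (cmd == "run") {
      if (length(pos) < 1L) stop2("run needs a series path")
      mode <- if (!is.null(opt[["vdp-mode"]]))
        c(rv = "regional_ventilation", fvl = "fvl")[[opt[["vdp-mode"]]]]
      else NULL
      cmd_run(pos[1], out_dir = opt$out, config_path = opt$config,
              mask_path = opt$mask,
              frame_interval_s = if (!is.null(opt[["frame-interval"]]))
                as.numeric(opt[["frame-interval"]]) else NULL,
              format = if (isTRUE(opt$dicom)) "dicom_dir" else "nifti",
              vdp_mode = mode)
    } else if (cmd == "stats") {
      if (length(pos) < 1L) stop2("stats needs a subject CSV path")
      cmd_stats(pos[1], out_dir = opt$out)
    } else {
      message("unknown command: ", cmd, "\n", usage)
      return(2L)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("^stage 'io'|file not found|required|needs ",
              conditionMessage(e))) 2L else 3L
  })
  res
}
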