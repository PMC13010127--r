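#' Construct a 2D+t image series
#'
#' Container for the dynamic single-slice series `S(x, t)`: a 3D array
#' (X x Y x T) with spatial and temporal metadata.
#'
#' @param frames numeric array X x Y x T (or X x Y x 1 x T, squeezed).
#' @param pixel_spacing_mm in-plane spacing, mm.
#' @param frame_interval_s temporal resolution, seconds (> 0).
#' @param identifier free-text series identifier.
#' @return object of class `image_series`.
#' @export
image_series <- function(frames, pixel_spacing_mm = c(1.7, 1.7),
                         frame_interval_s = 0.3, identifier = "series") {
  if (length(dim(frames)) == 4L) {
    if (dim(frames)[3] != 1L)
      stop2("multi-slice volumes are not supported; the pipeline is single-slice 2D+t")
    frames <- array(frames, dim(frames)[c(1, 2, 4)])
  }
  stopifnot(length(dim(frames)) == 3L)
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop2("frame_interval_s must be > 0")
  if (!all(is.finite(frames))) stop2("series contains non-finite values")
  structure(list(frames = frames,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 frame_interval_s = frame_interval_s,
                 identifier = as.character(identifier)),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_series '%s'> %d x %d, %d frames @ %.3g s (%.1f s)\n",
              x$identifier, d[1], d[2], d[3], x$frame_interval_s,
              (d[3] - 1) * x$frame_interval_s))
  invisible(x)
}

#' Number of frames / spatial grid of a series
#'
#' @param series an [image_series()].
#' @return integer count, or length-2 integer vector `c(X, Y)`.
#' @export
n_frames <- function(series) dim(series$frames)[3]

#' @rdname n_frames
#' @export
grid_shape <- function(series) dim(series$frames)[1:2]

#' Read a dynamic series from disk
#'
#' @param path NIfTI file (`.nii`/`.nii.gz`) or a DICOM series directory.
#' @param format `"nifti"` or `"dicom_dir"`.
#' @param frame_interval_s explicit override for the temporal resolution;
#'   required if the header carries none.
#' @return an [image_series()].
#' @export
read_series <- function(path, format = c("nifti", "dicom_dir"),
                        frame_interval_s = NULL) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!file.exists(path)) stop2("file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[3] != 1L)
      stop2("3D multi-slice volume; the pipeline is single-slice 2D+t")
    hdr <- RNifti::niftiHeader(img)
    pd <- RNifti::pixdim(img)
    if (length(d) == 3L) img <- array(img, c(d[1], d[2], 1L, d[3]))
    # trust the temporal spacing only when the header declares a time unit
    # (xyzt_units bits 3-5); a bare pixdim[4] of 1 is the NIfTI placeholder
    has_time_unit <- bitwAnd(hdr$xyzt_units, 56L) != 0L
    # for a 3D (X x Y x T) file the temporal spacing is pixdim slot 3
    tslot <- if (length(d) == 3L) 3L else 4L
    dt <- frame_interval_s %||%
      if (length(pd) >= tslot && pd[tslot] > 0 && has_time_unit)
        pd[tslot] else NULL
    if (is.null(dt))
      stop2("no temporal metadata in NIfTI header; pass frame_interval_s explicitly")
    image_series(array(as.numeric(img), dim(img)),
                 pixel_spacing_mm = pd[1:2], frame_interval_s = dt,
                 identifier = sub("\\.nii(\\.gz)?$", "", basename(path)))
  } else {
    read_dicom_series(path, frame_interval_s = frame_interval_s)
  }
}

#' Write a series as NIfTI (X x Y x 1 x T)
#'
#' @param series an [image_series()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_series <- function(series, path) {
  d <- dim(series$frames)
  arr <- array(series$frames, c(d[1], d[2], 1L, d[3]))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$pixel_spacing_mm, 1,
                           series$frame_interval_s)
  img$xyzt_units <- 10L # millimetres + seconds
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write a binary mask as NIfTI
#'
#' Masks are stored as 0/1 integers aligned voxel-for-voxel with the series.
#' @param mask logical matrix.
#' @param path file path.
#' @param pixel_spacing_mm in-plane spacing recorded in the header.
#' @export
write_mask <- function(mask, path, pixel_spacing_mm = c(1.7, 1.7)) {
  img <- RNifti::asNifti(array(as.integer(mask), c(dim(mask), 1L)))
  RNifti::pixdim(img) <- c(pixel_spacing_mm, 1)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  matrix(as.numeric(img) > 0, d[1], d[2])
}

#' Quantitative per-voxel map
#'
#' @param values numeric matrix; `NA` marks no-data voxels.
#' @param kind `"ventilation_pct"`, `"perfusion_pct"` or `"fvl_correlation"`.
#' @param mask logical analysis mask the map is defined on; defaults to the
#'   non-`NA` voxels of `values`.
#' @return object of class `quant_map`.
#' @export
quant_map <- function(values,
                      kind = c("ventilation_pct", "perfusion_pct",
                               "fvl_correlation"),
                      mask = !is.na(values)) {
  choices <- c("ventilation_pct", "perfusion_pct", "fvl_correlation")
  if (length(kind) > 1L) kind <- kind[1]
  if (!kind %in% choices)
    stop2("unknown map kind: ", kind, " (expected one of ",
          paste(choices, collapse = ", "), ")")
  stopifnot(all(dim(values) == dim(mask)))
  v <- values[mask & !is.na(values)]
  if (kind == "fvl_correlation") {
    stopifnot(all(v >= -1 - 1e-9 & v <= 1 + 1e-9))
  } else {
    stopifnot(all(is.finite(v)))
  }
  structure(list(values = values, kind = kind, mask = mask),
            class = "quant_map")
}

#' Write a quantitative map as NIfTI
#'
#' No-data voxels are written as NaN.
#' @param map a [quant_map()].
#' @param path file path.
#' @param pixel_spacing_mm spacing recorded in the header.
#' @export
write_map <- function(map, path, pixel_spacing_mm = c(1.7, 1.7)) {
  img <- RNifti::asNifti(array(map$values, c(dim(map$values), 1L)))
  RNifti::pixdim(img) <- c(pixel_spacing_mm, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_map
#' @param kind,mask see [quant_map()]; supplied on read since NIfTI does not
#'   carry them.
#' @export
read_map <- function(path, kind, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  values <- matrix(as.numeric(img), d[1], d[2])
  if (is.null(mask)) mask <- !is.na(values)
  quant_map(values, kind = kind, mask = mask)
}

#' Lung-level report measures in canonical column order
#'
#' @return character vector: mean normalized ventilation (`V`), mean
#'   normalized perfusion (`Q`), defect percentages (`VDP`, `QDP`) and the
#'   ventilation/perfusion match categories.
#' @export
report_columns <- function() {
  c("V", "Q", "VDP", "QDP", "VQM_defect", "VQM_non_defect")
}

#' Write a metrics report as JSON and CSV
#'
#' The CSV carries one column per lung-level measure (Table-style
#' abbreviations: V, Q, VDP, QDP, VQM_defect, VQM_non_defect) plus
#' provenance; the JSON carries the full report including category areas and
#' the thresholds used.
#'
#' @param report a `metrics_report` (see [compute_metrics()]), or a list of
#'   them for a multi-row CSV; an empty list writes a header-only CSV.
#' @param path_json,path_csv output paths (either may be `NULL` to skip).
#' @export
write_report <- function(report, path_json = NULL, path_csv = NULL) {
  reports <- if (inherits(report, "metrics_report")) list(report) else report
  if (!is.null(path_json)) {
    payload <- if (length(reports) == 1L) unclass(reports[[1]]) else
      lapply(reports, unclass)
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  if (!is.null(path_csv)) {
    cols <- c("series_id", report_columns(), "config_hash")
    if (length(reports) == 0L) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                   cols))
    } else {
      df <- do.call(rbind, lapply(reports, function(r) {
        data.frame(series_id = r$series_id %||% NA_character_,
                   V = r$mean_ventilation, Q = r$mean_perfusion,
                   VDP = r$vdp, QDP = r$qdp, VQM_defect = r$vqm_defect,
                   VQM_non_defect = r$vqm_nondefect,
                   config_hash = r$config_hash %||% NA_character_)
      }))
      names(df) <- cols
    }
    write.csv(df, path_csv, row.names = FALSE)
  }
  invisible(list(json = path_json, csv = path_csv))
}

#' Read a subject table
#'
#' Plain CSV with columns `id`, `group` (HV / LOPD), spirometry in percent
#' predicted (`vc_percent`, `fvc_percent`, `fev1_percent`, `pef_percent`),
#' `niv` (logical), and any number of numeric metric columns (e.g. the
#' functional-MRI measures). Unknown columns are preserved.
#'
#' @param path CSV file path.
#' @return data.frame with validated core columns.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop2("subject table is empty")
  required <- c("id", "group")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop2("subject table lacks required columns: ",
          paste(missing, collapse = ", "))
  if (any(!nzchar(df$id)) || any(!nzchar(df$group)))
    stop2("id and group must be non-empty")
  pct <- intersect(c("vc_percent", "fvc_percent", "fev1_percent",
                     "pef_percent", report_columns()), names(df))
  for (p in pct)
    if (any(df[[p]] < 0, na.rm = TRUE)) stop2(p, " has negative values")
  if ("niv" %in% names(df)) df$niv <- as.logical(df$niv)
  df
}

#' Run configuration
#'
#' All tunable analysis settings, serializable to YAML losslessly.
#'
#' @param quant a [quantification_config()].
#' @param resp_lowpass_hz respiratory low-pass cutoff (default 0.5 Hz).
#' @param cardiac_band_hz cardiac band-pass, Hz (default 0.6-2.0; clipped to
#'   Nyquist at run time).
#' @param n_bins phase bins for both reconstructed cycles (default 15).
#' @param registration list of registration settings (`alpha`, `n_iter`,
#'   `n_levels`, `n_warp`).
#' @param percentile_type quantile convention tag (R type 7 = linear
#'   interpolation between closest ranks).
#' @param seed integer seed recorded with every run.
#' @return object of class `run_config`.
#' @export
run_config <- function(quant = quantification_config(),
                       resp_lowpass_hz = 0.5,
                       cardiac_band_hz = c(0.6, 2.0),
                       n_bins = 15L,
                       registration = list(alpha = 2, n_iter = 120L,
                                           n_levels = 3L, n_warp = 2L),
                       percentile_type = 7L,
                       seed = 1L) {
  stopifnot(n_bins >= 5L, resp_lowpass_hz > 0,
            length(cardiac_band_hz) == 2L,
            cardiac_band_hz[1] > 0, cardiac_band_hz[2] > cardiac_band_hz[1])
  structure(list(quant = quant, resp_lowpass_hz = resp_lowpass_hz,
                 cardiac_band_hz = as.numeric(cardiac_band_hz),
                 n_bins = as.integer(n_bins), registration = registration,
                 percentile_type = as.integer(percentile_type),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(quant = do.call(quantification_config, y$quant),
             resp_lowpass_hz = y$resp_lowpass_hz,
             cardiac_band_hz = unlist(y$cardiac_band_hz),
             n_bins = y$n_bins, registration = y$registration,
             percentile_type = y$percentile_type, seed = y$seed)
}

#' Short digest of a run configuration for provenance fields
#'
#' @param config a [run_config()].
#' @return 8-hex-digit character scalar; equal configurations hash equally.
#' @export
config_hash <- function(config) {
  # order-stable digest of the serialized config (no external digest package)
  s <- yaml::as.yaml(unclass(config))
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", h)
}
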