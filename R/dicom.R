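# Minimal DICOM series-directory reader: explicit-VR little-endian files
# with uncompressed 16-bit pixel data, which covers exported dynamic 2D
# series. Only the tags the pipeline needs are interpreted; everything else
# is skipped structurally.

dcm_wanted <- c(
  "0008,0032" = "acq_time",        # AcquisitionTime (TM)
  "0020,0013" = "instance_number", # InstanceNumber (IS)
  "0028,0010" = "rows",            # Rows (US)
  "0028,0011" = "cols",            # Columns (US)
  "0028,0030" = "pixel_spacing",   # PixelSpacing (DS)
  "0028,0100" = "bits_allocated",  # BitsAllocated (US)
  "0028,0103" = "pixel_rep",       # PixelRepresentation (US)
  "7fe0,0010" = "pixel_data")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop2("not a DICOM part-10 file: ", path)
  pos <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) as.integer(raw[p]) + 256 * as.integer(raw[p + 1L]) +
    65536 * as.integer(raw[p + 2L]) + 16777216 * as.integer(raw[p + 3L])
  while (pos + 7L <= length(raw)) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); data_start <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_start <- pos + 8L
    }
    tag <- sprintf("%04x,%04x", grp, ele)
    if (tag %in% names(dcm_wanted)) {
      field <- dcm_wanted[[tag]]
      bytes <- raw[data_start:(data_start + len - 1L)]
      out[[field]] <- switch(field,
        rows = , cols = , bits_allocated = , pixel_rep =
          as.integer(bytes[1]) + 256L * as.integer(bytes[2]),
        instance_number = as.integer(trimws(rawToChar(bytes))),
        acq_time = trimws(rawToChar(bytes)),
        pixel_spacing = as.numeric(strsplit(trimws(rawToChar(bytes)),
                                            "\\\\")[[1]]),
        pixel_data = bytes)
      if (field == "pixel_data") break
    }
    pos <- data_start + len
  }
  if (is.null(out$pixel_data) || is.null(out$rows) || is.null(out$cols))
    stop2("missing Rows/Columns/PixelData in ", path)
  ba <- out$bits_allocated %||% 16L
  if (ba != 16L) stop2("only 16-bit DICOM pixel data supported")
  px <- readBin(out$pixel_data, "integer", n = out$rows * out$cols,
                size = 2L, signed = isTRUE(out$pixel_rep == 1L),
                endian = "little")
  if (!isTRUE(out$pixel_rep == 1L)) px <- px %% 65536L # unsigned
  # DICOM stores row-major (rows of the image); R fills column-major, so the
  # matrix is built cols x rows giving [x, y] indexing
  out$image <- matrix(px, nrow = out$cols, ncol = out$rows)
  out
}

# TM value "HHMMSS.FFFFFF" -> seconds since midnight
dcm_time_seconds <- function(tm) {
  if (is.null(tm) || !nzchar(tm)) return(NA_real_)
  hh <- as.numeric(substr(tm, 1, 2)); mm <- as.numeric(substr(tm, 3, 4))
  ss <- as.numeric(substring(tm, 5))
  hh * 3600 + mm * 60 + ss
}

read_dicom_series <- function(dir, frame_interval_s = NULL) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L) stop2("no DICOM series found in ", dir)
  objs <- lapply(files, read_dicom_file)
  times <- vapply(objs, function(o) dcm_time_seconds(o$acq_time), 0)
  inst <- vapply(objs, function(o) o$instance_number %||% NA_integer_, 0L)
  ord <- if (all(is.finite(times))) order(times, inst) else order(inst)
  objs <- objs[ord]; times <- times[ord]
  shp <- dim(objs[[1]]$image)
  if (!all(vapply(objs, function(o) all(dim(o$image) == shp), TRUE)))
    stop2("inconsistent frame shapes in DICOM series")
  dt <- frame_interval_s
  if (is.null(dt) && all(is.finite(times)) && length(unique(times)) > 1L)
    dt <- median(diff(times))
  if (is.null(dt) || !is.finite(dt) || dt <= 0)
    stop2("no temporal metadata in DICOM series; pass frame_interval_s explicitly")
  frames <- array(0, c(shp[1], shp[2], length(objs)))
  for (k in seq_along(objs)) frames[, , k] <- objs[[k]]$image
  ps <- objs[[1]]$pixel_spacing %||% c(1, 1)
  image_series(frames, pixel_spacing_mm = rev(ps), frame_interval_s = dt,
               identifier = basename(dir))
}
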