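# Tiny explicit-VR little-endian DICOM writer used only to build synthetic
# series directories for reader tests.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")

dcm_element <- function(group, element, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2L == 1L) { # DICOM values are even-length
    pad <- if (vr %in% c("OB", "UI")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad); len <- len + 1L
  }
  head <- c(dcm_u16(group), dcm_u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_u32(len), value_raw)
  } else {
    c(head, dcm_u16(len), value_raw)
  }
}

write_test_dicom <- function(path, image, instance_number, acq_time,
                             pixel_spacing = c(1.7, 1.7)) {
  # image: matrix [x, y]. DICOM pixel data is row-major with Rows = ny and
  # Columns = nx, so each DICOM row is image[, y] — the column-major flatten.
  px <- writeBin(as.integer(image), raw(), size = 2, endian = "little")
  body <- c(
    dcm_element(0x0008, 0x0032, "TM", charToRaw(acq_time)),
    dcm_element(0x0020, 0x0013, "IS", charToRaw(as.character(instance_number))),
    dcm_element(0x0028, 0x0010, "US", dcm_u16(ncol(image))), # Rows
    dcm_element(0x0028, 0x0011, "US", dcm_u16(nrow(image))), # Columns
    dcm_element(0x0028, 0x0030, "DS",
                charToRaw(paste(rev(pixel_spacing), collapse = "\\"))),
    dcm_element(0x0028, 0x0100, "US", dcm_u16(16L)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16(0L)),
    dcm_element(0x7fe0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
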