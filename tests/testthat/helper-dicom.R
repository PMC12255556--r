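# Minimal explicit-VR little-endian DICOM writer, used only to build test
# fixtures for the reader.

.raw_uint <- function(x, size) {
  out <- raw(size)
  for (i in seq_len(size)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

.dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  head <- c(.raw_uint(group, 2), .raw_uint(element, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, raw(2), .raw_uint(length(value_raw), 4), value_raw)
  } else {
    c(head, .raw_uint(length(value_raw), 2), value_raw)
  }
}

write_minimal_dicom <- function(path, pixels, spacing = c(1, 1),
                                instance = 1L, series_uid = "1.2.3.4",
                                slice_location = NA, slope = NA, intercept = NA) {
  stopifnot(all(pixels >= 0), all(pixels == round(pixels)), all(pixels < 65536))
  txt <- function(x) charToRaw(as.character(x))
  body <- c(
    .dcm_element(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1")),
    .dcm_element(0x0020, 0x000E, "UI", charToRaw(series_uid)),
    .dcm_element(0x0020, 0x0013, "IS", txt(instance)))
  if (!is.na(slice_location))
    body <- c(body, .dcm_element(0x0020, 0x1041, "DS", txt(slice_location)))
  body <- c(body,
    .dcm_element(0x0028, 0x0010, "US", .raw_uint(nrow(pixels), 2)),
    .dcm_element(0x0028, 0x0011, "US", .raw_uint(ncol(pixels), 2)))
  if (!any(is.na(spacing)))
    body <- c(body, .dcm_element(0x0028, 0x0030, "DS",
                                 charToRaw(paste(spacing, collapse = "\\"))))
  body <- c(body, .dcm_element(0x0028, 0x0100, "US", .raw_uint(16, 2)))
  if (!is.na(intercept))
    body <- c(body, .dcm_element(0x0028, 0x1052, "DS", txt(intercept)))
  if (!is.na(slope))
    body <- c(body, .dcm_element(0x0028, 0x1053, "DS", txt(slope)))
  # row-major pixel order
  vals <- as.integer(t(pixels))
  px <- unlist(lapply(vals, .raw_uint, size = 2))
  body <- c(body, .dcm_element(0x7FE0, 0x0010, "OW", px))
  writeBin(c(raw(128), charToRaw("DICM"), body), path)
  invisible(path)
}
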