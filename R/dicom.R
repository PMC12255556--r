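# Minimal DICOM reader for uncompressed little-endian single-frame files.
# Covers exactly the tags the QA pipeline needs; compressed transfer
# syntaxes and sequences of undefined length are rejected with an error.

.dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

.dcm_uint <- function(raw, size) {
  sum(as.integer(raw[seq_len(size)]) * 256^(seq_len(size) - 1))
}

# Parse one DICOM file, returning the pixel matrix and header fields.
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L  # 1-based offset just past the preamble + marker
  explicit <- TRUE
  transfer_syntax <- "1.2.840.10008.1.2.1"
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  fields <- list()

  read_elem <- function(pos, explicit) {
    group <- .dcm_uint(raw[pos:(pos + 1L)], 2L)
    element <- .dcm_uint(raw[(pos + 2L):(pos + 3L)], 2L)
    pos <- pos + 4L
    vr <- NA_character_
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- .dcm_uint(raw[(pos + 4L):(pos + 7L)], 4L)
        pos <- pos + 8L
      } else {
        len <- .dcm_uint(raw[(pos + 2L):(pos + 3L)], 2L)
        pos <- pos + 4L
      }
    } else {
      len <- .dcm_uint(raw[pos:(pos + 3L)], 4L)
      pos <- pos + 4L
    }
    if (len == 0xFFFFFFFF)
      stop("undefined-length DICOM elements are not supported: ", path)
    list(group = group, element = element, vr = vr, len = len,
         value_start = pos, next_pos = pos + len)
  }

  repeat {
    if (pos > length(raw)) break
    el <- read_elem(pos, explicit)
    tag <- .dcm_tag(el$group, el$element)
    val_raw <- if (el$len > 0L) raw[el$value_start:(el$next_pos - 1L)] else raw(0)
    if (tag == "0002,0010") {
      transfer_syntax <- sub("\\x00*$", "", rawToChar(val_raw))
      transfer_syntax <- trimws(transfer_syntax)
    }
    fields[[tag]] <- list(vr = el$vr, raw = val_raw)
    pos <- el$next_pos
    if (el$group == 0x0002 && pos <= length(raw)) {
      nxt_group <- .dcm_uint(raw[pos:(pos + 1L)], 2L)
      if (nxt_group != 0x0002) {
        if (transfer_syntax == "1.2.840.10008.1.2") {
          explicit <- FALSE
        } else if (transfer_syntax == "1.2.840.10008.1.2.1") {
          explicit <- TRUE
        } else {
          stop("unsupported DICOM transfer syntax '", transfer_syntax,
               "' (only uncompressed little endian is supported): ", path)
        }
      }
    }
    if (tag == "7FE0,0010") break  # pixel data is last
  }

  get_str <- function(tag) {
    f <- fields[[tag]]
    if (is.null(f)) return(NA_character_)
    trimws(sub("\\x00*$", "", rawToChar(f$raw)))
  }
  get_us <- function(tag) {
    f <- fields[[tag]]
    if (is.null(f)) return(NA_integer_)
    as.integer(.dcm_uint(f$raw, 2L))
  }

  rows <- get_us("0028,0010")
  cols <- get_us("0028,0011")
  bits <- get_us("0028,0100")
  if (is.na(rows) || is.na(cols)) stop("DICOM file lacks Rows/Columns: ", path)
  if (is.na(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated ", bits, ": ", path)
  px <- fields[["7FE0,0010"]]
  if (is.null(px)) stop("DICOM file lacks pixel data: ", path)
  size <- bits %/% 8L
  vals <- readBin(px$raw, "integer", n = rows * cols, size = size,
                  signed = FALSE, endian = "little")
  if (length(vals) < rows * cols) stop("truncated pixel data: ", path)
  # DICOM pixel order is row-major
  mat <- t(matrix(as.numeric(vals), nrow = cols, ncol = rows))

  spacing_str <- get_str("0028,0030")
  spacing <- if (is.na(spacing_str)) NULL else as.numeric(strsplit(spacing_str, "\\\\")[[1]])
  slope <- suppressWarnings(as.numeric(get_str("0028,1053")))
  intercept <- suppressWarnings(as.numeric(get_str("0028,1052")))
  if (!is.na(slope) || !is.na(intercept)) {
    mat <- mat * (if (is.na(slope)) 1 else slope) +
      (if (is.na(intercept)) 0 else intercept)
  }

  list(pixels = mat,
       pixel_spacing_mm = spacing,
       instance_number = suppressWarnings(as.integer(get_str("0020,0013"))),
       series_uid = get_str("0020,000E"),
       slice_location = suppressWarnings(as.numeric(get_str("0020,1041"))))
}

# Read a directory of single-frame DICOM files as one series.
read_dicom_series <- function(dir, slice_count = NULL) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[file.info(files)$isdir %in% FALSE]
  if (length(files) == 0L) stop("no DICOM frames found in ", dir)
  frames <- lapply(files, read_dicom_file)

  uids <- unique(vapply(frames, `[[`, "", "series_uid"))
  uids <- uids[!is.na(uids)]
  if (length(uids) > 1L)
    stop("mixed series UIDs in one directory: ", paste(uids, collapse = ", "))

  spacings <- lapply(frames, `[[`, "pixel_spacing_mm")
  if (any(vapply(spacings, is.null, TRUE)))
    stop("pixel spacing absent in DICOM header")
  spacing <- spacings[[1L]]
  if (!all(vapply(spacings, function(s) isTRUE(all.equal(s, spacing)), TRUE)))
    stop("inconsistent pixel spacing across DICOM frames")

  inst <- vapply(frames, function(f) {
    if (is.na(f$instance_number)) .Machine$integer.max else f$instance_number
  }, 0L)
  loc <- vapply(frames, function(f) {
    if (is.na(f$slice_location)) 0 else f$slice_location
  }, 0)
  ord <- order(inst, loc)
  frames <- frames[ord]
  loc <- loc[ord]

  locs <- sort(unique(loc))
  ns <- if (!is.null(slice_count)) as.integer(slice_count) else max(1L, length(locs))
  if (length(locs) > 2L) {
    gaps <- diff(locs)
    if (max(gaps) - min(gaps) > 1e-3 * max(abs(gaps)))
      stop("non-uniform slice spacing across DICOM frames")
  }
  nfile <- length(frames)
  if (nfile %% ns != 0L)
    stop("number of DICOM frames (", nfile, ") is not a multiple of the slice count (", ns, ")")
  nf <- nfile %/% ns

  dims <- dim(frames[[1L]]$pixels)
  voxels <- array(0, c(nf, ns, dims[1L], dims[2L]))
  k <- 1L
  for (f in seq_len(nf)) {
    for (s in seq_len(ns)) {
      m <- frames[[k]]$pixels
      if (!identical(dim(m), dims)) stop("inconsistent image dimensions across DICOM frames")
      voxels[f, s, , ] <- m
      k <- k + 1L
    }
  }
  list(voxels = voxels, pixel_spacing_mm = spacing)
}
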