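#' Read a phantom image series from disk
#'
#' Reads a NIfTI-1 file or a directory of single-frame DICOM files into a
#' [phantom_series()]. NIfTI arrays are interpreted as
#' `(row, col, frame)` when 3-D and `(row, col, slice, frame)` when 4-D;
#' pixel spacing is taken from the header `pixdim` fields. DICOM frames are
#' sorted by instance number then slice position, rescale slope/intercept
#' are applied when present, and a directory mixing several series UIDs is
#' rejected.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or a DICOM directory.
#' @param format `"auto"` (directory implies DICOM), `"nifti"` or `"dicom"`.
#' @param frame_role Role of the frame axis; `"auto"` classifies a series
#'   with 10 or more frames as an EPI time series and shorter ones as
#'   spin-echo repetitions.
#' @param pe_axis Phase-encode axis (explicit configuration; see
#'   [phantom_series()]).
#' @param slice_count For DICOM input only: number of slices per frame when
#'   slice positions are absent from the headers.
#' @return A [phantom_series()].
#' @export
read_series <- function(path, format = c("auto", "nifti", "dicom"),
                        frame_role = c("auto", "se_repetition", "epi_volume"),
                        pe_axis = c("row", "col"), slice_count = NULL) {
  format <- match.arg(format)
  frame_role <- match.arg(frame_role)
  pe_axis <- match.arg(pe_axis)
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (format == "auto") format <- if (dir.exists(path)) "dicom" else "nifti"

  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    nd <- length(dim(arr))
    pd <- RNifti::pixdim(img)
    spacing <- abs(pd[1:2])
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("pixel spacing absent or invalid in NIfTI header")
    if (nd == 3L) {
      # single slice, frames along the 3rd dimension
      voxels <- aperm(arr, c(3L, 1L, 2L))
      d <- dim(voxels)
      voxels <- array(voxels, c(d[1L], 1L, d[2L], d[3L]))
    } else if (nd == 4L) {
      voxels <- aperm(arr, c(4L, 3L, 1L, 2L))
    } else {
      stop("NIfTI input must be 3-D or 4-D, got ", nd, " dimensions")
    }
  } else {
    dcm <- read_dicom_series(path, slice_count = slice_count)
    voxels <- dcm$voxels
    spacing <- dcm$pixel_spacing_mm
  }

  if (frame_role == "auto")
    frame_role <- if (dim(voxels)[1L] >= 10L) "epi_volume" else "se_repetition"
  phantom_series(voxels, spacing, pe_axis = pe_axis, frame_role = frame_role)
}

#' Write a phantom series to a NIfTI-1 file
#'
#' Inverse of [read_series()] for the NIfTI container: the voxel array and
#' pixel spacing survive a write/read round trip exactly (data are stored
#' as float64).
#'
#' @param series A [phantom_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "phantom_series"))
  d <- dim(series$voxels)
  if (d[2L] == 1L) {
    arr <- aperm(array(series$voxels, d[c(1L, 3L, 4L)]), c(2L, 3L, 1L))
    pd <- c(series$pixel_spacing_mm, 1)
  } else {
    arr <- aperm(series$voxels, c(3L, 4L, 2L, 1L))
    pd <- c(series$pixel_spacing_mm, 1, 1)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
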