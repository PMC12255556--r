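#' Construct a phantom image series
#'
#' The internal container for all analyses: a stack of magnitude images of
#' the phantom, stored as a 4-D array indexed `(frame, slice, row, col)`.
#' A frame is either one spin-echo repetition or one EPI volume.
#'
#' @param voxels Numeric array of non-negative magnitude values. Either 4-D
#'   `(frame, slice, row, col)` or 3-D `(frame, row, col)` for a
#'   single-slice series (a slice dimension of length 1 is inserted).
#' @param pixel_spacing_mm Numeric length-2 vector: in-plane pixel spacing
#'   in mm along the row and column axes.
#' @param pe_axis Phase-encode axis, `"row"` or `"col"`. Ghosting
#'   propagates along this axis; it decides which background ROIs are
#'   labelled PE vs FE. Taken from acquisition protocol configuration,
#'   never inferred from image headers.
#' @param frame_role `"se_repetition"` for a multi-repetition spin-echo
#'   series, `"epi_volume"` for an EPI time series.
#' @return An object of class `phantom_series`.
#' @seealso [read_series()], [simulate_se()], [simulate_epi()]
#' @export
phantom_series <- function(voxels, pixel_spacing_mm, pe_axis = c("row", "col"),
                           frame_role = c("se_repetition", "epi_volume")) {
  pe_axis <- match.arg(pe_axis)
  frame_role <- match.arg(frame_role)
  if (length(dim(voxels)) == 3L) {
    d <- dim(voxels)
    voxels <- array(voxels, c(d[1L], 1L, d[2L], d[3L]))
  }
  if (length(dim(voxels)) != 4L)
    stop("'voxels' must be a 3-D (frame, row, col) or 4-D (frame, slice, row, col) array")
  if (anyNA(voxels) || any(voxels < 0))
    stop("magnitude voxel values must be finite and non-negative")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop("'pixel_spacing_mm' must be two positive numbers (row, col)")
  if (frame_role == "se_repetition" && dim(voxels)[1L] < 2L)
    stop("a spin-echo series needs at least 2 repetitions")
  structure(
    list(voxels = voxels,
         pixel_spacing_mm = pixel_spacing_mm,
         pe_axis = pe_axis,
         frame_role = frame_role),
    class = "phantom_series")
}

#' @export
print.phantom_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<phantom_series> %s: %d frame(s) x %d slice(s) x %dx%d px\n",
              x$frame_role, d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  pixel spacing %.4f x %.4f mm, phase-encode axis: %s\n",
              x$pixel_spacing_mm[1L], x$pixel_spacing_mm[2L], x$pe_axis))
  invisible(x)
}

#' Number of frames / slices in a series
#' @param series A [phantom_series()].
#' @return Integer count.
#' @export
n_frames <- function(series) dim(series$voxels)[1L]

#' @rdname n_frames
#' @export
n_slices <- function(series) dim(series$voxels)[2L]

#' Extract one 2-D image from a series
#'
#' @param series A [phantom_series()].
#' @param frame,slice 1-based frame and slice indices.
#' @return A numeric matrix `(row, col)`.
#' @export
get_slice <- function(series, frame = 1L, slice = 1L) {
  d <- dim(series$voxels)
  if (frame < 1L || frame > d[1L]) stop("frame index out of range")
  if (slice < 1L || slice > d[2L]) stop("slice index out of range")
  series$voxels[frame, slice, , ]
}
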