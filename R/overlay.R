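#' Save a mask-overlay image for visual QA
#'
#' Renders the image with the ROI outlines drawn on top (signal circle,
#' extreme-intensity ROIs, background rectangles, central square) and
#' writes it as a PNG, for the visual sanity check that usually accompanies
#' automated masking.
#'
#' @param image 2-D magnitude image the ROIs belong to.
#' @param roi A `roi_geometry` from [build_structural_rois()], or any named
#'   list of logical mask matrices.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_roi_overlay <- function(image, roi, path) {
  masks <- Filter(function(m) is.matrix(m) && is.logical(m), roi)
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(1, 1, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  nr <- nrow(image); nc <- ncol(image)
  # row 1 at the top, matching radiological screen layout
  graphics::image(seq_len(nc), seq_len(nr), t(image[nr:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  xlab = "", ylab = "", useRaster = TRUE)
  cols <- rep(c("blue", "green", "yellow", "red", "red", "red", "red", "red"),
              length.out = length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    graphics::contour(seq_len(nc), seq_len(nr),
                      t(m[nr:1, , drop = FALSE]) * 1, levels = 0.5,
                      add = TRUE, drawlabels = FALSE, col = cols[i], lwd = 2)
  }
  invisible(path)
}
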