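#' Detected phantom circle
#'
#' @param center_row,center_col Sub-pixel centre coordinates (1-based pixel
#'   units; the centre of pixel `[i, j]` is at `(i, j)`).
#' @param radius Radius in pixels, `> 5`.
#' @param dim Image dimensions `(rows, cols)` the circle must fit inside.
#' @return An object of class `phantom_circle`.
#' @export
phantom_circle <- function(center_row, center_col, radius, dim) {
  if (!is.finite(radius) || radius <= 5)
    stop("implausible phantom radius (<= 5 px); detection failed")
  if (center_row - radius < 0.5 || center_row + radius > dim[1L] + 0.5 ||
      center_col - radius < 0.5 || center_col + radius > dim[2L] + 0.5)
    stop("fitted phantom circle extends beyond the image bounds")
  structure(list(center_row = center_row, center_col = center_col,
                 radius = radius, dim = as.integer(dim)),
            class = "phantom_circle")
}

#' @export
print.phantom_circle <- function(x, ...) {
  cat(sprintf("<phantom_circle> center (%.2f, %.2f) px, radius %.2f px\n",
              x$center_row, x$center_col, x$radius))
  invisible(x)
}

# Deterministic Otsu threshold on a 256-bin histogram.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) stop("phantom not found: constant image")
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- -Inf
  # threshold at the upper edge of the winning bin so that every value
  # binned into the lower class is excluded by `image > threshold`
  breaks[which.max(between) + 1L]
}

# Algebraic (Kasa) least-squares circle fit to edge coordinates.
kasa_circle_fit <- function(rows, cols) {
  z <- rows^2 + cols^2
  coef <- qr.solve(cbind(rows, cols, 1), z)
  cr <- coef[1L] / 2
  cc <- coef[2L] / 2
  r <- sqrt(coef[3L] + cr^2 + cc^2)
  c(center_row = unname(cr), center_col = unname(cc), radius = unname(r))
}

#' Detect the phantom's circular edge
#'
#' Segments the single bright circular object in a magnitude image and fits
#' a circle to its edge: Otsu threshold, largest connected component, hole
#' filling, extraction of boundary pixels, and an algebraic least-squares
#' (Kasa) circle fit. Boundary pixel centres sit on average half a pixel
#' inside the true edge, so half a pixel is added to the fitted radius.
#' The result is deterministic for a fixed image.
#'
#' @param image 2-D non-negative matrix containing one bright, roughly
#'   circular object on a dark background.
#' @return A [phantom_circle()] with sub-pixel centre and radius.
#' @export
detect_phantom <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix")
  if (all(image == image[1L])) stop("phantom not found: constant image")
  thr <- otsu_threshold(image)
  mask <- image > thr
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0L || max(sizes) < 0.01 * length(image))
    stop("phantom not found: no foreground component covering >= 1% of the image")
  comp <- lab == which.max(sizes)
  nr <- nrow(comp); nc <- ncol(comp)
  if (any(comp[1L, ]) && any(comp[nr, ]) && any(comp[, 1L]) && any(comp[, nc]))
    stop("phantom not separable from background: foreground touches all image borders")
  comp <- EBImage::fillHull(comp) > 0

  # boundary pixels: in the component with a 4-neighbour outside it
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- comp
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  edge <- which(comp & !interior, arr.ind = TRUE)
  fit <- kasa_circle_fit(as.numeric(edge[, 1L]), as.numeric(edge[, 2L]))
  phantom_circle(fit["center_row"], fit["center_col"], fit["radius"] + 0.5,
                 dim = c(nr, nc))
}

# Boolean disk mask in pixel units.
circle_mask <- function(dim, center_row, center_col, radius_px) {
  dr <- (seq_len(dim[1L]) - center_row)^2
  dc <- (seq_len(dim[2L]) - center_col)^2
  outer(dr, dc, `+`) <= radius_px^2
}

# Offsets (drow, dcol) of a circular kernel of the given physical area.
# Anisotropic spacing yields an elliptical pixel footprint of the circular
# physical kernel.
kernel_offsets <- function(pixel_spacing_mm, area_mm2) {
  r_mm <- sqrt(area_mm2 / pi)
  max_dr <- floor(r_mm / pixel_spacing_mm[1L])
  max_dc <- floor(r_mm / pixel_spacing_mm[2L])
  g <- expand.grid(dr = -max_dr:max_dr, dc = -max_dc:max_dc)
  keep <- (g$dr * pixel_spacing_mm[1L])^2 + (g$dc * pixel_spacing_mm[2L])^2 <= r_mm^2
  as.matrix(g[keep, , drop = FALSE])
}

# Sum of `img` over the kernel at every center (invalid centers NA), plus
# the count of kernel pixels falling inside `mask` at every center.
.kernel_scan <- function(img, mask, offsets) {
  nr <- nrow(img); nc <- ncol(img)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  m <- matrix(0L, nr, nc)
  m[mask] <- 1L
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1L]; dc <- offsets[k, 2L]
    r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
    c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
    if (r1 > r2 || c1 > c2) next
    acc[r1:r2, c1:c2] <- acc[r1:r2, c1:c2] + img[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
    cnt[r1:r2, c1:c2] <- cnt[r1:r2, c1:c2] + m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  }
  list(sum = acc, inside = cnt)
}

# Smallest (row, col) in lexicographic order among candidate indices.
.lex_first <- function(cand) {
  cand[order(cand[, 1L], cand[, 2L])[1L], , drop = TRUE]
}

#' Locate the minimal- and maximal-intensity small ROIs
#'
#' Slides a circular kernel of the given physical area (~1 cm^2 by default)
#' over every position where it lies fully inside the large signal ROI, and
#' returns the positions and kernel means of the minimal and maximal mean
#' signal intensity. Ties are broken by the smallest `(row, col)` position.
#'
#' @param image 2-D spin-echo magnitude image.
#' @param large_circle_mask Logical matrix: the large signal ROI.
#' @param pixel_spacing_mm Pixel spacing `(row, col)` in mm.
#' @param roi_area_mm2 Kernel area in mm^2 (default 100 = 1 cm^2).
#' @return List with `min_center`, `max_center` (row/col vectors), `s_min`,
#'   `s_max` (kernel means), `min_mask`, `max_mask` (logical matrices),
#'   `kernel_px` (pixels per kernel) and `achieved_area_mm2`.
#' @export
locate_extreme_rois <- function(image, large_circle_mask, pixel_spacing_mm,
                                roi_area_mm2 = 100) {
  off <- kernel_offsets(pixel_spacing_mm, roi_area_mm2)
  nk <- nrow(off)
  scan <- .kernel_scan(image, large_circle_mask, off)
  valid <- large_circle_mask & scan$inside == nk
  if (!any(valid)) stop("signal ROI too small for the extreme-intensity kernel")
  means <- scan$sum / nk
  means[!valid] <- NA_real_
  mn <- min(means, na.rm = TRUE)
  mx <- max(means, na.rm = TRUE)
  min_center <- .lex_first(which(valid & means == mn, arr.ind = TRUE))
  max_center <- .lex_first(which(valid & means == mx, arr.ind = TRUE))
  stamp <- function(center) {
    m <- matrix(FALSE, nrow(image), ncol(image))
    m[cbind(center[1L] + off[, 1L], center[2L] + off[, 2L])] <- TRUE
    m
  }
  list(min_center = unname(min_center), max_center = unname(max_center),
       s_min = mn, s_max = mx,
       min_mask = stamp(min_center), max_mask = stamp(max_center),
       kernel_px = nk,
       achieved_area_mm2 = nk * prod(pixel_spacing_mm))
}

# One background rectangle hugging the given side ("top","bottom","left",
# "right"), ~area_mm2, long side parallel to the hugged edge, 4:1 aspect,
# inset `inset` px from the border, clipped to stay `inset` px from the
# perpendicular borders.
.bg_rectangle <- function(dim, circle, pixel_spacing_mm, side, area_mm2,
                          inset = 2L) {
  px_area <- prod(pixel_spacing_mm)
  area_px <- area_mm2 / px_area
  short <- max(1L, round(sqrt(area_px / 4)))
  long <- max(1L, round(area_px / short))
  nr <- dim[1L]; nc <- dim[2L]
  cr <- round(circle$center_row); cc <- round(circle$center_col)
  # clearance: rectangle must stay >= 3 px away from the circle edge so it
  # is disjoint from the phantom mask dilated by 2 px
  gap_needed <- inset + short
  ok <- switch(side,
    top    = circle$center_row - circle$radius - 3 >= gap_needed,
    bottom = nr - (circle$center_row + circle$radius + 3) + 1 >= gap_needed,
    left   = circle$center_col - circle$radius - 3 >= gap_needed,
    right  = nc - (circle$center_col + circle$radius + 3) + 1 >= gap_needed)
  if (!ok) stop("insufficient background margin for a ", area_mm2, " mm^2 rectangle (", side, ")")
  m <- matrix(FALSE, nr, nc)
  if (side %in% c("top", "bottom")) {
    rows <- if (side == "top") (inset + 1L):(inset + short) else (nr - inset - short + 1L):(nr - inset)
    cols <- (cc - floor(long / 2)):(cc - floor(long / 2) + long - 1L)
    cols <- cols[cols > inset & cols <= nc - inset]
    m[rows, cols] <- TRUE
  } else {
    cols <- if (side == "left") (inset + 1L):(inset + short) else (nc - inset - short + 1L):(nc - inset)
    rows <- (cr - floor(long / 2)):(cr - floor(long / 2) + long - 1L)
    rows <- rows[rows > inset & rows <= nr - inset]
    m[rows, cols] <- TRUE
  }
  m
}

#' Square ROI mask centred on the phantom
#'
#' @param dim Image dimensions `(rows, cols)`.
#' @param center_row,center_col Phantom centre; rounded to the nearest pixel.
#' @param size Side length in pixels (default 15, giving a 225-pixel ROI).
#' @return Logical matrix.
#' @export
square_roi_mask <- function(dim, center_row, center_col, size = 15L) {
  cr <- round(center_row); cc <- round(center_col)
  half <- floor(size / 2)
  rows <- (cr - half):(cr - half + size - 1L)
  cols <- (cc - half):(cc - half + size - 1L)
  if (min(rows) < 1L || max(rows) > dim[1L] || min(cols) < 1L || max(cols) > dim[2L])
    stop("square ROI extends beyond the image bounds")
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[rows, cols] <- TRUE
  m
}

#' Build all structural-analysis ROIs
#'
#' Constructs the full ROI geometry used by the structural metrics: a large
#' circular signal ROI with a diameter equal to 80% of the phantom's
#' diameter, two ~1 cm^2 circular ROIs at the locations of minimal and
#' maximal mean intensity inside it, four ~10 cm^2 background rectangles
#' outside the phantom (one pair along the frequency-encode axis, one along
#' the phase-encode axis), and the 15x15 pixel central square ROI.
#'
#' @param circle A [phantom_circle()] from [detect_phantom()].
#' @param se_image The 2-D spin-echo image the extreme-intensity ROIs are
#'   searched on.
#' @param pixel_spacing_mm Pixel spacing `(row, col)` in mm.
#' @param pe_axis Phase-encode axis: background rectangles along this axis
#'   are the PE pair, the perpendicular pair is FE.
#' @param small_roi_area_mm2,bg_area_mm2 Target physical ROI areas in mm^2.
#' @return An object of class `roi_geometry`: logical masks
#'   `large_circle_mask`, `min_roi_mask`, `max_roi_mask`, `bg_fe1`,
#'   `bg_fe2`, `bg_pe1`, `bg_pe2`, `square_roi_mask`, plus `pixel_area_mm2`,
#'   achieved areas, extreme-ROI centres/means and the input circle.
#' @export
build_structural_rois <- function(circle, se_image, pixel_spacing_mm,
                                  pe_axis = c("row", "col"),
                                  small_roi_area_mm2 = 100, bg_area_mm2 = 1000) {
  pe_axis <- match.arg(pe_axis)
  stopifnot(inherits(circle, "phantom_circle"))
  dim <- dim(se_image)
  large <- circle_mask(dim, circle$center_row, circle$center_col,
                       0.8 * circle$radius)
  ext <- locate_extreme_rois(se_image, large, pixel_spacing_mm,
                             roi_area_mm2 = small_roi_area_mm2)
  rect <- function(side) .bg_rectangle(dim, circle, pixel_spacing_mm, side, bg_area_mm2)
  # the PE pair lies along the phase-encode axis from the phantom
  if (pe_axis == "row") {
    bg_pe1 <- rect("top");  bg_pe2 <- rect("bottom")
    bg_fe1 <- rect("left"); bg_fe2 <- rect("right")
  } else {
    bg_pe1 <- rect("left"); bg_pe2 <- rect("right")
    bg_fe1 <- rect("top");  bg_fe2 <- rect("bottom")
  }
  structure(list(
    circle = circle,
    large_circle_mask = large,
    min_roi_mask = ext$min_mask, max_roi_mask = ext$max_mask,
    min_center = ext$min_center, max_center = ext$max_center,
    s_min = ext$s_min, s_max = ext$s_max,
    bg_fe1 = bg_fe1, bg_fe2 = bg_fe2, bg_pe1 = bg_pe1, bg_pe2 = bg_pe2,
    square_roi_mask = square_roi_mask(dim, circle$center_row, circle$center_col),
    pixel_area_mm2 = prod(pixel_spacing_mm),
    small_roi_area_mm2 = ext$achieved_area_mm2,
    bg_area_mm2 = vapply(list(bg_fe1, bg_fe2, bg_pe1, bg_pe2), sum, 0L) *
      prod(pixel_spacing_mm)
  ), class = "roi_geometry")
}
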