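#' Select the analysis frames and slice of an EPI series
#'
#' Discards the initial volumes (two by default, leaving 198 of a standard
#' 200-volume run) and keeps the central slice, index `floor(n/2) + 1`
#' (slice 14 of 27).
#'
#' @param series A [phantom_series()] with `frame_role = "epi_volume"`.
#' @param discard Number of leading volumes to drop (steady-state
#'   approach); default 2.
#' @param slice 1-based slice index, or `NULL` for the central slice.
#' @return A single-slice [phantom_series()] with the remaining volumes.
#' @export
select_analysis_frames <- function(series, discard = 2L, slice = NULL) {
  stopifnot(inherits(series, "phantom_series"))
  if (series$frame_role != "epi_volume")
    stop("temporal analysis requires an EPI volume series, not '",
         series$frame_role, "'")
  nf <- n_frames(series)
  if (nf < discard + 2L)
    stop("fewer volumes (", nf, ") than discard count + 2")
  if (is.null(slice)) slice <- floor(n_slices(series) / 2) + 1L
  if (slice < 1L || slice > n_slices(series)) stop("slice index out of range")
  keep <- (discard + 1L):nf
  voxels <- series$voxels[keep, slice, , , drop = FALSE]
  d <- dim(voxels)
  out <- phantom_series(array(voxels, c(d[1L], 1L, d[3L], d[4L])),
                        series$pixel_spacing_mm, pe_axis = series$pe_axis,
                        frame_role = "epi_volume")
  attr(out, "slice_used") <- as.integer(slice)
  out
}

# Coerce a series or (frame, row, col) array to a 3-D stack.
.epi_stack <- function(epi) {
  if (inherits(epi, "phantom_series")) {
    d <- dim(epi$voxels)
    if (d[2L] != 1L)
      stop("temporal computations operate on a single slice; run select_analysis_frames() first")
    return(array(epi$voxels, d[c(1L, 3L, 4L)]))
  }
  if (length(dim(epi)) != 3L) stop("expected a (frame, row, col) stack")
  epi
}

#' Temporal mean (signal) image
#'
#' Pixel-by-pixel average across all analysis volumes.
#'
#' @param epi A single-slice EPI [phantom_series()] or a
#'   `(frame, row, col)` array.
#' @return A 2-D matrix.
#' @export
compute_signal_image <- function(epi) {
  stack <- .epi_stack(epi)
  if (dim(stack)[1L] < 2L) stop("need at least 2 frames")
  colMeans(stack, dims = 1L)
}

# Orthonormal quadratic design (intercept, centred linear, quadratic) for a
# length-V time index; centring/scaling only conditions the fit, the fitted
# values equal those of a naive polynomial regression.
.quad_basis <- function(v) {
  t_idx <- seq_len(v)
  u <- (t_idx - mean(t_idx)) / v
  qr.Q(qr(cbind(1, u, u^2)))
}

#' Second-order polynomial detrending
#'
#' Ordinary least-squares fit of a quadratic polynomial in the (centred)
#' time index; the residual carries the temporal fluctuation and the
#' fitted trend carries slow drift.
#'
#' @param series Numeric vector (one time series), length >= 3.
#' @return An object of class `detrend_result`: `residual`, `trend`,
#'   `trend_max`, `trend_min` and `mean_level` (the mean of the input
#'   series).
#' @export
detrend_quadratic <- function(series) {
  v <- length(series)
  if (v < 3L) stop("underdetermined fit: need at least 3 time points")
  q <- .quad_basis(v)
  trend <- as.vector(q %*% crossprod(q, series))
  structure(list(residual = series - trend, trend = trend,
                 trend_max = max(trend), trend_min = min(trend),
                 mean_level = mean(series)),
            class = "detrend_result")
}

#' Temporal fluctuation noise (TFN) image
#'
#' Pixel-by-pixel sample standard deviation of the quadratic-detrended
#' time series.
#'
#' @inheritParams compute_signal_image
#' @return A 2-D matrix of per-pixel residual SDs.
#' @export
compute_tfn_image <- function(epi) {
  stack <- .epi_stack(epi)
  d <- dim(stack)
  v <- d[1L]
  if (v < 4L) stop("need at least 4 frames for a residual SD after a quadratic fit")
  y <- matrix(stack, nrow = v)                # V x (R*C), pixels as columns
  q <- .quad_basis(v)
  res <- y - q %*% crossprod(q, y)
  # residuals of a fit including an intercept have exactly zero mean
  matrix(sqrt(colSums(res^2) / (v - 1)), d[2L], d[3L])
}

#' SFNR image and summary
#'
#' Divides the signal image by the TFN image pixel by pixel. Pixels with
#' zero temporal fluctuation are set to `NA` in the SFNR image and excluded
#' from the summary, which is the mean SFNR over the central square ROI.
#'
#' @param signal_image,tfn_image Matrices from [compute_signal_image()] and
#'   [compute_tfn_image()].
#' @param square_roi_mask Logical matrix, the 15x15 central ROI.
#' @return List with `sfnr_image`, `sfnr_summary` and `n_excluded` (ROI
#'   pixels without a valid SFNR value).
#' @export
compute_sfnr <- function(signal_image, tfn_image, square_roi_mask) {
  stopifnot(identical(dim(signal_image), dim(tfn_image)),
            identical(dim(signal_image), dim(square_roi_mask)))
  sfnr <- signal_image / tfn_image
  sfnr[tfn_image <= 0] <- NA_real_
  vals <- sfnr[square_roi_mask]
  if (all(is.na(vals))) stop("no valid SFNR pixels in the signal ROI")
  list(sfnr_image = sfnr, sfnr_summary = mean(vals, na.rm = TRUE),
       n_excluded = sum(is.na(vals)))
}

# Spatially averaged ROI time series of a stack.
.roi_series <- function(stack, mask) {
  v <- dim(stack)[1L]
  y <- matrix(stack, nrow = v)
  rowMeans(y[, as.vector(mask), drop = FALSE])
}

#' Percent fluctuation
#'
#' Spatially averages the square ROI per volume, detrends the resulting
#' series with a second-order polynomial, and reports
#' `100 * SD(residual) / M`, `M` being the mean of the spatially averaged
#' series.
#'
#' @inheritParams compute_signal_image
#' @param square_roi_mask Logical matrix, the central square ROI.
#' @return Percent fluctuation (percent; multiply by 10 for per mille).
#' @export
compute_percent_fluctuation <- function(epi, square_roi_mask) {
  stack <- .epi_stack(epi)
  if (!any(square_roi_mask)) stop("empty ROI")
  dt <- detrend_quadratic(.roi_series(stack, square_roi_mask))
  100 * sd(dt$residual) / dt$mean_level
}

#' Signal drift
#'
#' `100 * (trend_max - trend_min) / M` of the second-order polynomial
#' trend fitted to the spatially averaged square-ROI series, capturing slow
#' signal change over the run (e.g. gradient-heating field drift).
#'
#' @inheritParams compute_percent_fluctuation
#' @return Drift in percent.
#' @export
compute_drift <- function(epi, square_roi_mask) {
  stack <- .epi_stack(epi)
  if (!any(square_roi_mask)) stop("empty ROI")
  dt <- detrend_quadratic(.roi_series(stack, square_roi_mask))
  100 * (dt$trend_max - dt$trend_min) / dt$mean_level
}

# Row/col ranges of the N x N ROI: for odd N centred on the centre pixel,
# for even N the centre pixel sits at (0-based) offset floor(N/2), i.e. the
# ROI extends one pixel further towards lower indices.
.square_range <- function(center, n) (center - floor(n / 2)) + 0:(n - 1L)

#' Weisskoff analysis and radius of decorrelation
#'
#' For square ROIs of side length `N = 1..max_n` centred on the phantom
#' centre pixel, computes the spatially averaged time series, detrends it
#' with a second-order polynomial, and records the residual SD
#' `SD_actual(N)` and the series mean `M_N`. Under pixelwise-independent
#' noise `SD(N) = SD(1)/N`, so the log-log plot of SD against N is a
#' declining straight line; spatially coherent scanner instability makes
#' the actual curve flatten. The radius of decorrelation is
#' `RDC = (SD_actual(1)/M_1) / (SD_actual(max_n)/M_max_n)`; larger values
#' indicate better temporal stability. The estimate is reported as
#' computed, without clamping; a value above `max_n` (possible by sampling
#' noise) triggers a warning.
#'
#' @inheritParams compute_signal_image
#' @param center A [phantom_circle()] or numeric `(row, col)` centre. The
#'   centre is rounded to the nearest pixel and shared by all N. When a
#'   circle is given, a ROI reaching outside the phantom is an error.
#' @param max_n Largest ROI side length (default 15).
#' @return An object of class `weisskoff_curve`: `side_lengths`,
#'   `sd_actual`, `roi_means`, `sd_theoretical` (= `sd_actual[1]/N`),
#'   `rdc` and `n_volumes`.
#' @export
weisskoff_analysis <- function(epi, center, max_n = 15L) {
  stack <- .epi_stack(epi)
  d <- dim(stack)
  if (inherits(center, "phantom_circle")) {
    cr <- round(center$center_row); cc <- round(center$center_col)
    half_diag <- sqrt(2) * (floor(max_n / 2) + 1)
    if (half_diag > center$radius)
      stop("ROI outside phantom: ", max_n, "x", max_n,
           " ROI exceeds the phantom boundary")
  } else {
    cr <- round(center[1L]); cc <- round(center[2L])
  }
  rows <- .square_range(cr, max_n); cols <- .square_range(cc, max_n)
  if (min(rows) < 1L || max(rows) > d[2L] || min(cols) < 1L || max(cols) > d[3L])
    stop("ROI outside phantom: largest ROI exceeds the image bounds")

  ns <- seq_len(max_n)
  sd_actual <- roi_means <- numeric(max_n)
  for (n in ns) {
    block <- stack[, .square_range(cr, n), .square_range(cc, n), drop = FALSE]
    series <- apply(block, 1L, mean)
    dt <- detrend_quadratic(series)
    sd_actual[n] <- sd(dt$residual)
    roi_means[n] <- dt$mean_level
  }
  rdc <- (sd_actual[1L] / roi_means[1L]) / (sd_actual[max_n] / roi_means[max_n])
  if (is.finite(rdc) && rdc > max_n)
    warning(sprintf("RDC estimate %.2f exceeds the largest ROI side length %d; ",
                    rdc, max_n),
            "the decorrelation radius is beyond the measured range", call. = FALSE)
  structure(list(side_lengths = ns, sd_actual = sd_actual,
                 roi_means = roi_means,
                 sd_theoretical = sd_actual[1L] / ns,
                 rdc = rdc, n_volumes = d[1L]),
            class = "weisskoff_curve")
}

#' @export
print.weisskoff_curve <- function(x, ...) {
  cat(sprintf("<weisskoff_curve> N = 1..%d over %d volumes, RDC = %.2f\n",
              max(x$side_lengths), x$n_volumes, x$rdc))
  invisible(x)
}

#' Plot a Weisskoff curve
#'
#' Log-log plot of the relative fluctuation `100 * SD_actual(N) / M_N`
#' (solid line with points) against the ROI side length, with the
#' theoretical pixelwise-independence prediction
#' `100 * SD_actual(1) / (N * M_1)` as a dashed line.
#'
#' @param x A `weisskoff_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.weisskoff_curve <- function(x, ...) {
  rel <- 100 * x$sd_actual / x$roi_means
  theo <- 100 * x$sd_theoretical / x$roi_means[1L]
  graphics::plot(x$side_lengths, rel, log = "xy", type = "o", pch = 16,
                 xlab = "ROI side length N (px)",
                 ylab = "Relative SD (%)", ...)
  graphics::lines(x$side_lengths, theo, lty = 2)
  graphics::legend("bottomleft", legend = c("measured", "theoretical 1/N"),
                   lty = c(1, 2), pch = c(16, NA), bty = "n")
  invisible(x)
}

#' Run the full temporal stability analysis
#'
#' Applies [select_analysis_frames()], detects the phantom on the temporal
#' mean image, places the 15x15 central ROI, and computes all temporal
#' metrics: signal image, TFN image, SFNR image and summary, percent
#' fluctuation, drift, and the Weisskoff curve with its radius of
#' decorrelation.
#'
#' @param series A [phantom_series()] with `frame_role = "epi_volume"`.
#' @param discard,slice Passed to [select_analysis_frames()].
#' @param roi_size Side of the central square ROI (default 15 px).
#' @param max_n Largest Weisskoff ROI side length (default 15).
#' @return An object of class `temporal_metrics`: images `signal_image`,
#'   `tfn_image`, `sfnr_image`; scalars `sfnr_summary`,
#'   `fluctuation_percent`, `fluctuation_permille`, `drift_percent`,
#'   `rdc`, `n_volumes`, `slice_used`; and the `weisskoff` curve.
#' @export
run_temporal <- function(series, discard = 2L, slice = NULL, roi_size = 15L,
                         max_n = 15L) {
  sel <- select_analysis_frames(series, discard = discard, slice = slice)
  stack <- .epi_stack(sel)
  signal_image <- compute_signal_image(stack)
  circle <- detect_phantom(signal_image)
  roi <- square_roi_mask(dim(signal_image), circle$center_row,
                         circle$center_col, size = roi_size)
  tfn_image <- compute_tfn_image(stack)
  sfnr <- compute_sfnr(signal_image, tfn_image, roi)
  fluct <- compute_percent_fluctuation(stack, roi)
  weisskoff <- weisskoff_analysis(stack, circle, max_n = max_n)
  structure(list(
    signal_image = signal_image, tfn_image = tfn_image,
    sfnr_image = sfnr$sfnr_image,
    sfnr_summary = sfnr$sfnr_summary,
    fluctuation_percent = fluct, fluctuation_permille = 10 * fluct,
    drift_percent = compute_drift(stack, roi),
    weisskoff = weisskoff, rdc = weisskoff$rdc,
    n_volumes = dim(stack)[1L],
    slice_used = attr(sel, "slice_used"),
    circle = circle
  ), class = "temporal_metrics")
}

#' @export
print.temporal_metrics <- function(x, ...) {
  cat("<temporal_metrics>\n")
  cat(sprintf("  SFNR summary      %.1f\n", x$sfnr_summary))
  cat(sprintf("  fluctuation       %.4f %% (%.4f per mille)\n",
              x$fluctuation_percent, x$fluctuation_permille))
  cat(sprintf("  drift             %.4f %%\n", x$drift_percent))
  cat(sprintf("  RDC               %.2f (over %d volumes)\n", x$rdc, x$n_volumes))
  invisible(x)
}
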