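# Independent brute-force oracles, deliberately naive: plain loops and
# stats::lm, sharing no code with the package internals.

# Kernel-mean scan over every center where the physical circular kernel
# lies fully inside `mask`; returns min/max centers (lexicographic
# tie-break) and their means.
brute_extreme_rois <- function(image, mask, spacing, area_mm2 = 100) {
  r_mm <- sqrt(area_mm2 / pi)
  offs <- list()
  for (dr in -floor(r_mm / spacing[1]):floor(r_mm / spacing[1]))
    for (dc in -floor(r_mm / spacing[2]):floor(r_mm / spacing[2]))
      if ((dr * spacing[1])^2 + (dc * spacing[2])^2 <= r_mm^2)
        offs[[length(offs) + 1]] <- c(dr, dc)
  best_min <- list(val = Inf, at = NULL)
  best_max <- list(val = -Inf, at = NULL)
  for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image))) {
    vals <- numeric(0); ok <- TRUE
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > nrow(image) || cc < 1 || cc > ncol(image) || !mask[rr, cc]) {
        ok <- FALSE; break
      }
      vals <- c(vals, image[rr, cc])
    }
    if (!ok) next
    m <- mean(vals)
    if (m < best_min$val) best_min <- list(val = m, at = c(r, c))
    if (m > best_max$val) best_max <- list(val = m, at = c(r, c))
  }
  list(min_center = best_min$at, max_center = best_max$at,
       s_min = best_min$val, s_max = best_max$val)
}

# Naive quadratic detrend of one series via stats::lm.
brute_detrend <- function(y) {
  t <- seq_along(y)
  fit <- stats::lm(y ~ t + I(t^2))
  list(residual = unname(stats::residuals(fit)),
       trend = unname(stats::fitted(fit)))
}

# Per-pixel temporal fluctuation noise via per-pixel lm fits.
brute_tfn <- function(stack) {
  d <- dim(stack)
  out <- matrix(0, d[2], d[3])
  for (r in seq_len(d[2])) for (c in seq_len(d[3]))
    out[r, c] <- stats::sd(brute_detrend(stack[, r, c])$residual)
  out
}

# Middle expression of the Weisskoff relation evaluated by double loop:
# R[i, j] are per-pixel quadratic-fit residuals; the per-volume ROI mean of
# R minus the grand mean R-bar, squared, summed over volumes, / (V - 1).
brute_weisskoff_sd <- function(stack, rows, cols) {
  v <- dim(stack)[1]
  px <- expand.grid(r = rows, c = cols)
  R <- sapply(seq_len(nrow(px)),
              function(j) brute_detrend(stack[, px$r[j], px$c[j]])$residual)
  roi_mean <- rowMeans(R)
  rbar <- mean(R)
  sqrt(sum((roi_mean - rbar)^2) / (v - 1))
}

# ROI statistics recomputed with explicit per-pixel loops.
brute_mask_mean <- function(image, mask) {
  tot <- 0; n <- 0
  for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image)))
    if (mask[r, c]) { tot <- tot + image[r, c]; n <- n + 1 }
  tot / n
}
brute_mask_sd <- function(image, mask) {
  vals <- c()
  for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image)))
    if (mask[r, c]) vals <- c(vals, image[r, c])
  stats::sd(vals)
}

# Boolean disk mask built independently of the package's mask helpers.
circle_mask_for_test <- function(dim, cr, cc, radius) {
  outer((seq_len(dim[1]) - cr)^2, (seq_len(dim[2]) - cc)^2, `+`) <= radius^2
}

# A plain synthetic disk image, independent of the package simulator.
disk_image <- function(nr, nc, cr, cc, radius, value = 100) {
  img <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if ((r - cr)^2 + (c - cc)^2 <= radius^2) img[r, c] <- value
  img
}
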