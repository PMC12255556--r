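test_that("frame selection discards leading volumes and picks the central slice", {
  s <- phantom_series(array(1, c(200, 27, 8, 8)), c(3.4375, 3.4375),
                      frame_role = "epi_volume")
  sel <- select_analysis_frames(s)
  expect_equal(n_frames(sel), 198)
  expect_equal(attr(sel, "slice_used"), 14)  # centre of 27 slices
  expect_error(select_analysis_frames(
    phantom_series(array(1, c(2, 1, 4, 4)), c(1, 1), frame_role = "epi_volume")),
    "fewer volumes")
  expect_error(select_analysis_frames(
    phantom_series(array(1, c(2, 1, 4, 4)), c(1, 1))),
    "EPI volume series")
})

test_that("signal image equals the per-pixel temporal mean", {
  expect_equal(compute_signal_image(array(7, c(5, 3, 3))), matrix(7, 3, 3))
  # frames alternating 0 and 2 average to 1 everywhere
  alt <- array(0, c(8, 3, 3)); alt[seq(2, 8, 2), , ] <- 2
  expect_equal(compute_signal_image(alt), matrix(1, 3, 3))
  set.seed(2)
  stack <- array(runif(6 * 4 * 4), c(6, 4, 4))
  want <- matrix(0, 4, 4)
  for (r in 1:4) for (c in 1:4) want[r, c] <- mean(stack[, r, c])
  expect_equal(compute_signal_image(stack), want, tolerance = 1e-15)
})

test_that("quadratic detrending nests quadratics and preserves noise", {
  t <- 1:198
  y <- 5 + 0.3 * t - 0.002 * t^2
  dt <- detrend_quadratic(y)
  expect_lt(max(abs(dt$residual)), 1e-9)
  expect_equal(dt$trend, y, tolerance = 1e-9)
  const <- detrend_quadratic(rep(4.2, 50))
  expect_equal(const$trend_max, const$trend_min)
  # residual mean is numerically zero
  set.seed(1)
  z <- rnorm(198)
  dtz <- detrend_quadratic(z)
  expect_lt(abs(mean(dtz$residual)), 1e-9 * sd(z))
  # white noise keeps its SD (3 dof lost out of 198)
  sds <- replicate(40, sd(detrend_quadratic(rnorm(198))$residual))
  expect_lt(abs(mean(sds) - 1), 0.05)
  expect_error(detrend_quadratic(c(1, 2)), "underdetermined")
})

test_that("detrending matches the naive polynomial regression", {
  set.seed(14)
  y <- 100 + cumsum(rnorm(60, 0, 0.1))
  got <- detrend_quadratic(y)
  want <- brute_detrend(y)
  expect_equal(got$residual, want$residual, tolerance = 1e-10)
  expect_equal(got$trend, want$trend, tolerance = 1e-10)
})

test_that("TFN image equals brute-force per-pixel detrended SDs", {
  set.seed(8)
  stack <- array(100 + rnorm(30 * 4 * 4, sd = 2), c(30, 4, 4))
  expect_equal(compute_tfn_image(stack), brute_tfn(stack), tolerance = 1e-12)
  # noiseless drifting stack -> all-zero TFN
  t <- 1:30
  drifting <- outer(1 + 0.001 * t + 1e-5 * t^2, matrix(50, 4, 4))
  dim(drifting) <- c(30, 4, 4)
  expect_lt(max(compute_tfn_image(drifting)), 1e-10)
})

test_that("TFN recovers iid temporal noise", {
  set.seed(15)
  stack <- array(100 + rnorm(198 * 8 * 8, sd = 2), c(198, 8, 8))
  tfn <- compute_tfn_image(stack)
  expect_lt(abs(mean(tfn) - 2) / 2, 0.01)
  expect_true(all(abs(tfn - 2) / 2 < 0.35))
})

test_that("SFNR divides signal by fluctuation and handles degenerate pixels", {
  sig <- matrix(400, 20, 20)
  tfn <- matrix(1, 20, 20)
  mask <- square_roi_mask(c(20, 20), 10, 10, 15)
  got <- compute_sfnr(sig, tfn, mask)
  expect_equal(got$sfnr_summary, 400)
  # scale invariance
  got2 <- compute_sfnr(2 * sig, 2 * tfn, mask)
  expect_equal(got2$sfnr_summary, 400)
  # zero-fluctuation pixels are excluded and counted
  tfn[10, 10] <- 0
  got3 <- compute_sfnr(sig, tfn, mask)
  expect_equal(got3$n_excluded, 1)
  expect_equal(got3$sfnr_summary, 400)
  expect_error(compute_sfnr(sig, matrix(0, 20, 20), mask), "no valid SFNR")
})

test_that("percent fluctuation matches the closed form of a sinusoidal modulation", {
  v <- 198
  t <- seq_len(v)
  eps <- 0.01
  series <- 100 * (1 + eps * sin(2 * pi * 12 * t / v))
  stack <- array(rep(series, times = 9), c(v, 3, 3))
  mask <- matrix(TRUE, 3, 3)
  # sine SD = amplitude / sqrt(2); the quadratic trend absorbs almost none
  expect_lt(abs(compute_percent_fluctuation(stack, mask) - 100 * eps / sqrt(2)) /
              (100 * eps / sqrt(2)), 0.05)
  # constant and purely quadratic series fluctuate by zero
  expect_lt(compute_percent_fluctuation(array(5, c(10, 2, 2)),
                                        matrix(TRUE, 2, 2)), 1e-10)
  quad <- array(rep(100 + 0.01 * t + 1e-4 * t^2, 4), c(v, 2, 2))
  expect_lt(compute_percent_fluctuation(quad, matrix(TRUE, 2, 2)), 1e-9)
})

test_that("drift reproduces a linear ramp's peak-to-peak height", {
  v <- 198
  series <- 100 + (seq_len(v) - 1) / (v - 1)  # total height 1 on mean ~100.5
  stack <- array(rep(series, 4), c(v, 2, 2))
  mask <- matrix(TRUE, 2, 2)
  drift <- compute_drift(stack, mask)
  expect_equal(drift, 100 * 1 / mean(series), tolerance = 1e-6)
  expect_lt(compute_drift(array(5, c(10, 2, 2)), matrix(TRUE, 2, 2)), 1e-10)
})

test_that("Weisskoff analysis obeys its limiting cases", {
  set.seed(30)
  v <- 198
  # perfectly common fluctuation: averaging changes nothing, RDC = 1
  common <- rnorm(v, sd = 0.5)
  stack <- array(100 + rep(common, times = 31 * 31), c(v, 31, 31))
  wk <- weisskoff_analysis(stack, c(16, 16), max_n = 15)
  expect_equal(wk$sd_actual, rep(wk$sd_actual[1], 15), tolerance = 1e-10)
  expect_equal(wk$rdc, 1, tolerance = 1e-10)
  # N = 1: theoretical and actual curves coincide by construction
  expect_identical(wk$sd_theoretical[1], wk$sd_actual[1])
  expect_equal(wk$n_volumes, v)
})

test_that("ROI-mean residual SD matches the brute-force double-loop evaluation", {
  set.seed(31)
  stack <- array(100 + rnorm(40 * 9 * 9, sd = 1), c(40, 9, 9))
  for (n in c(1, 2, 3)) {
    rows <- (5 - floor(n / 2)) + 0:(n - 1)
    wk <- weisskoff_analysis(stack, c(5, 5), max_n = n)
    expect_equal(wk$sd_actual[n], brute_weisskoff_sd(stack, rows, rows),
                 tolerance = 1e-12)
  }
})

test_that("an RDC beyond the measured ROI range is reported with a warning", {
  # anti-correlated pixel pairs almost cancel in the ROI mean, driving the
  # apparent decorrelation radius far beyond the largest side length
  set.seed(32)
  v <- 40
  e <- rnorm(v); f <- rnorm(v)
  stack <- array(100, c(v, 3, 3))
  stack[, 1, 1] <- 100 + e;        stack[, 1, 2] <- 100 - 0.99 * e
  stack[, 2, 1] <- 100 + f;        stack[, 2, 2] <- 100 - 0.99 * f
  expect_warning(weisskoff_analysis(stack, c(2, 2), max_n = 2),
                 "exceeds the largest ROI side length")
})

test_that("Weisskoff ROIs must stay inside the phantom", {
  stack <- array(1, c(10, 16, 16))
  circ <- phantom_circle(8, 8, 6, c(16, 16))
  expect_error(weisskoff_analysis(stack, circ, max_n = 15), "ROI outside phantom")
})

test_that("temporal metrics are invariant under global intensity scaling", {
  epi <- simulate_epi(qa_scenario("epi", n_volumes = 60, seed = 6))
  tm1 <- run_temporal(epi)
  epi2 <- epi
  epi2$voxels <- epi$voxels * 3
  tm2 <- run_temporal(epi2)
  expect_equal(tm2$sfnr_summary, tm1$sfnr_summary, tolerance = 1e-10)
  expect_equal(tm2$fluctuation_percent, tm1$fluctuation_percent, tolerance = 1e-10)
  expect_equal(tm2$drift_percent, tm1$drift_percent, tolerance = 1e-10)
  expect_equal(tm2$rdc, tm1$rdc, tolerance = 1e-10)
})

test_that("the full temporal pipeline reports coherent fields", {
  tm <- run_temporal(simulate_epi(qa_scenario("epi", seed = 2)))
  expect_equal(tm$n_volumes, 198)
  expect_equal(tm$weisskoff$side_lengths, 1:15)
  expect_equal(tm$rdc, tm$weisskoff$rdc)
  expect_equal(tm$fluctuation_permille, 10 * tm$fluctuation_percent)
  ok <- tm$tfn_image > 0
  expect_equal(tm$sfnr_image[ok], (tm$signal_image / tm$tfn_image)[ok])
  expect_gte(tm$drift_percent, 0)
})
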