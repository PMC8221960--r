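test_that("peak estimation finds the IRF peak of a bright pixel", {
  g <- default_grid()
  sp <- array_spec(1L, 1L, peak_jitter_span_ns = 0, hot_pixel_fraction = 0,
                   dark_rate_per_bin = 0)
  f <- simulate_spad_frame(sp, tau_ns = NULL, photons_per_frame = 1e4,
                           rng_seed = 3)
  peaks <- estimate_peak_positions(f)
  expect_lte(abs(peaks[1, 1] - 50L), 1L)
})

test_that("a single photon defines the peak; empty pixels are flagged NA", {
  g <- default_grid()
  counts <- array(0, dim = c(1, 2, 300))
  counts[1, 1, 73] <- 1
  f <- structure(list(counts = counts,
                      true_peak_offsets = matrix(0L, 1, 2),
                      true_hot_mask = matrix(FALSE, 1, 2),
                      grid = g, array = array_spec(1L, 2L)),
                 class = "spad_frame")
  peaks <- estimate_peak_positions(f, smooth = FALSE)
  expect_equal(peaks[1, 1], 73L)
  expect_true(is.na(peaks[1, 2]))
  calib <- suppressWarnings(calibrate_array(f))
  expect_true(calib$hot_mask[1, 2])
})

test_that("peak map recovers the simulator's true offsets", {
  sp <- array_spec(40L, 40L, peak_jitter_span_ns = 2, hot_pixel_fraction = 0,
                   dark_rate_per_bin = 1e-4)
  f <- simulate_spad_frame(sp, tau_ns = NULL, photons_per_frame = 40 * 40 * 300,
                           irf = irf_spec(peak_bin = 100L), rng_seed = 8)
  peaks <- estimate_peak_positions(f)
  truth <- 100L + f$true_peak_offsets
  expect_gte(mean(abs(peaks - truth) <= 1L), 0.99)
})

test_that("hot-pixel detection hits the simulator's truth labels", {
  sp <- array_spec(64L, 64L, peak_jitter_span_ns = 0, hot_pixel_fraction = 0.01,
                   hot_pixel_rate_multiplier = 100, dark_rate_per_bin = 1e-4)
  f <- simulate_spad_frame(sp, tau_ns = 2, photons_per_frame = 64 * 64 * 100,
                           rng_seed = 9)
  mask <- detect_hot_pixels(f)
  truth <- f$true_hot_mask
  sens <- sum(mask & truth) / sum(truth)
  fpr <- sum(mask & !truth) / sum(!truth)
  expect_gte(sens, 0.99)
  expect_lte(fpr, 0.001)
})

test_that("hot-pixel rule flags a lone bright pixel and nothing else", {
  g <- sim_grid(10L, 0.04)
  counts <- array(1, dim = c(3, 3, 10))
  counts[2, 2, ] <- 100
  f <- structure(list(counts = counts, true_peak_offsets = matrix(0L, 3, 3),
                      true_hot_mask = matrix(FALSE, 3, 3), grid = g,
                      array = array_spec(3L, 3L)),
                 class = "spad_frame")
  mask <- detect_hot_pixels(f)
  expect_identical(which(mask), 5L)
  # identical pixels: nothing flagged
  counts[2, 2, ] <- 1
  f$counts <- counts
  expect_false(any(detect_hot_pixels(f)))
  # all-zero array warns
  f$counts <- array(0, dim = c(3, 3, 10))
  expect_warning(m0 <- detect_hot_pixels(f), "zero")
  expect_false(any(m0))
})

test_that("alignment shifts pixels onto the reference and conserves photons", {
  g <- sim_grid(60L, 0.04)
  base <- c(rep(0, 20), 5, 20, 5, rep(0, 37))
  counts <- array(0, dim = c(1, 2, 60))
  counts[1, 1, ] <- base
  counts[1, 2, ] <- c(rep(0, 3), base[1:57])  # +3 bins
  f <- structure(list(counts = counts, true_peak_offsets = matrix(c(0L, 3L), 1, 2),
                      true_hot_mask = matrix(FALSE, 1, 2), grid = g,
                      array = array_spec(1L, 2L)),
                 class = "spad_frame")
  calib <- pixel_calibration(matrix(c(22L, 25L), 1, 2),
                             matrix(FALSE, 1, 2), reference_bin = 22L)
  agg <- align_and_aggregate(f, calib)
  expect_equal(agg$counts, 2 * base)
  # masking a pixel removes its counts
  calib2 <- pixel_calibration(matrix(c(22L, 25L), 1, 2),
                              matrix(c(FALSE, TRUE), 1, 2), reference_bin = 22L)
  expect_equal(align_and_aggregate(f, calib2)$counts, base)
  # aligning an already-aligned frame is the identity
  calib3 <- pixel_calibration(matrix(c(22L, 22L), 1, 2),
                              matrix(FALSE, 1, 2), reference_bin = 22L)
  expect_equal(align_and_aggregate(f, calib3)$counts,
               counts[1, 1, ] + counts[1, 2, ])
  # photon accounting is exact: total = unmasked total - shifted-out counts
  expect_equal(agg$total_counts, sum(counts))
})

test_that("calibration collapses a jittered array IRF to a sharp peak", {
  sp <- array_spec(48L, 48L, peak_jitter_span_ns = 4, hot_pixel_fraction = 0.01,
                   hot_pixel_rate_multiplier = 100, dark_rate_per_bin = 1e-4)
  f <- simulate_spad_frame(sp, tau_ns = NULL, photons_per_frame = 48 * 48 * 400,
                           irf = irf_spec(peak_bin = 150L), rng_seed = 10)
  calib <- calibrate_array(f, reference_bin = 150L)
  before <- measure_fwhm(aggregate_unaligned(f, calib$hot_mask))
  after <- measure_fwhm(align_and_aggregate(f, calib))
  expect_gt(before, 3)
  expect_lte(after, 0.28)
})

test_that("background subtraction is exact for flat and shifted histograms", {
  g <- sim_grid(300L, 0.04)
  flat <- decay_histogram(rep(3.5, 300), g)
  expect_warning(out <- subtract_background(flat), "peak")
  expect_true(all(out$counts == 0))
  # linearity: decay + constant baseline recovers the decay (lead window
  # kept clear of the IRF rise)
  d <- ground_truth_decay(2, 5000, default_irf_curve(), g)
  shifted <- decay_histogram(d$counts + 7, g)
  rec <- subtract_background(shifted, n_lead_bins = 40L)
  expect_equal(rec$counts, d$counts, tolerance = 1e-3)
  expect_equal(attr(rec, "background_level"), 7, tolerance = 1e-3)
})

test_that("background subtraction improves CMM on dark-count contaminated decays", {
  g <- default_grid()
  irf <- default_irf_curve()
  cfg <- cmm_config(50L, 300L)
  irf_h <- decay_histogram(irf * 1e4, g)
  set.seed(21)
  err_raw <- err_sub <- numeric(100)
  for (i in 1:100) {
    d <- ground_truth_decay(2, 3000, irf, g)
    noisy <- decay_histogram(pmax(d$counts + 2 + rnorm(300), 0), g)
    est_raw <- cmm_lifetime(noisy, cfg, irf_h)$tau_ns
    est_sub <- cmm_lifetime(subtract_background(noisy), cfg, irf_h)$tau_ns
    err_raw[i] <- abs(est_raw - 2)
    err_sub[i] <- abs(est_sub - 2)
  }
  expect_lt(mean(err_sub), mean(err_raw))
})

test_that("FWHM measurement matches closed forms", {
  g <- sim_grid(300L, 0.04)
  t <- bin_times_ns(g)
  gauss <- decay_histogram(1e3 * exp(-(t - 6)^2 / (2 * 0.1^2)), g)
  expect_equal(measure_fwhm(gauss), 2 * sqrt(2 * log(2)) * 0.1,
               tolerance = 0.005 / 0.2355)
  irf_h <- decay_histogram(default_irf_curve() * 1e4, g)
  expect_equal(measure_fwhm(irf_h), 0.230, tolerance = 0.04 / 0.230)
  rect <- decay_histogram(c(rep(0, 100), rep(10, 25), rep(0, 175)), g)
  expect_equal(measure_fwhm(rect), 25 * 0.04, tolerance = 0.04 / 1)
  flat <- decay_histogram(rep(5, 300), g)
  expect_error(measure_fwhm(flat), "half maximum")
})
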