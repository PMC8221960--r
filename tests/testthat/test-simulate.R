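test_that("discretized IRF peaks at the requested bin and sums to one", {
  g <- default_grid()
  curve <- make_irf(irf_spec(), g)
  expect_equal(which.max(curve), 50L)
  expect_equal(sum(curve), 1)
  expect_false(attr(curve, "truncated"))
})

test_that("IRF FWHM on a 10x finer grid matches the nominal width", {
  fine <- sim_grid(3000L, 0.004)
  curve <- make_irf(irf_spec(fwhm_ns = 0.23, peak_bin = 500L), fine)
  h <- decay_histogram(curve * 1e6, fine)
  expect_equal(measure_fwhm(h), 0.230, tolerance = 0.004 / 0.230)
})

test_that("IRF too close to the window edge is flagged", {
  g <- sim_grid(100L, 0.04)
  expect_warning(curve <- make_irf(irf_spec(fwhm_ns = 1, peak_bin = 2L), g),
                 "truncated")
  expect_true(attr(curve, "truncated"))
})

test_that("ground-truth decays conserve the requested photon total", {
  g <- default_grid()
  irf <- default_irf_curve()
  for (tau in c(0.1, 0.7, 2.5, 5)) {
    for (nt in c(100, 5e3, 1e4)) {
      d <- ground_truth_decay(tau, nt, irf, g)
      expect_equal(d$total_counts, nt, tolerance = 1e-9)
    }
  }
  expect_error(ground_truth_decay(-1, 100, irf, g), "positive")
  expect_error(ground_truth_decay(2, 0, irf, g), "positive")
})

test_that("convolution with a delta IRF reproduces the bare exponential", {
  g <- sim_grid(200L, 0.04)
  p <- 30L
  d <- ground_truth_decay(1, 1000, delta_irf(p, g), g)
  expect_true(all(d$counts[seq_len(p - 1L)] == 0))
  tail_part <- d$counts[p:200]
  expected <- exp(-(seq_along(tail_part) - 1L) * 0.04 / 1)
  expect_equal(tail_part / tail_part[1], expected, tolerance = 1e-12)
})

test_that("decay centroid matches the truncated-exponential first moment", {
  # closed form: centroid of exp(-t/tau) on [0, T] is tau - T/(e^(T/tau)-1)
  g <- sim_grid(250L, 0.04)
  T_ <- grid_window_ns(g)
  for (tau in c(0.5, 1, 2)) {
    d <- ground_truth_decay(tau, 1e4, delta_irf(1L, g), g)
    oracle <- tau - T_ / (exp(T_ / tau) - 1)
    expect_equal(centroid_time_ns(d), oracle, tolerance = 1e-3)
  }
  d2 <- ground_truth_decay(2, 1e4, delta_irf(1L, g), g)
  expect_equal(centroid_time_ns(d2), 1.932, tolerance = 0.0005)
})

test_that("noise model is the identity when disabled and never negative", {
  g <- default_grid()
  d <- ground_truth_decay(2, 1000, default_irf_curve(), g)
  out <- add_noise(d, noise_spec(sigma = 0, poisson_enabled = FALSE),
                   rng_seed = 1)
  expect_identical(out$counts, d$counts)
  noisy <- add_noise(d, noise_spec(sigma = 50), rng_seed = 2)
  expect_true(all(noisy$counts >= 0))
  rounded <- add_noise(d, noise_spec(sigma = 5), rng_seed = 3,
                       round_counts = TRUE)
  expect_true(all(rounded$counts == floor(rounded$counts)))
})

test_that("noise model reproduces the analytic variance y + sigma^2", {
  # flat decay at y = 100, sigma = 5: per-bin variance should be 125
  g <- sim_grid(300L, 0.04)
  clean <- decay_histogram(rep(100, 300), g)
  set.seed(99)
  reps <- replicate(300, add_noise(clean, noise_spec(sigma = 5))$counts)
  v <- stats::var(as.vector(reps))  # 9e4 draws of the same law
  expect_equal(v, 125, tolerance = 0.05)
  expect_equal(mean(reps), 100, tolerance = 0.01)
})

test_that("dataset sampling honors the spec and is seed-deterministic", {
  g <- default_grid()
  irf <- default_irf_curve()
  spec <- dataset_spec(n_samples = 500L, seed = 7L)
  ds1 <- sample_dataset(spec, irf, g)
  expect_equal(sum(ds1$meta$split == "train"), 400L)
  expect_equal(sum(ds1$meta$split == "validation"), 100L)
  expect_true(all(ds1$meta$tau_ns > 0.1 & ds1$meta$tau_ns < 5))
  expect_true(all(ds1$meta$n_total >= 100 & ds1$meta$n_total <= 1e4))
  expect_true(all(ds1$meta$sigma <= ds1$meta$n_total / 300 + 1e-12))
  ds2 <- sample_dataset(spec, irf, g)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$meta, ds2$meta)
  one <- sample_dataset(dataset_spec(n_samples = 1L, seed = 1L), irf, g)
  expect_equal(nrow(one$counts), 1L)
})

test_that("sampled lifetimes are uniform on the stated range", {
  g <- default_grid()
  ds <- sample_dataset(dataset_spec(n_samples = 10000L, seed = 13L),
                       default_irf_curve(), g)
  ks <- stats::ks.test(ds$meta$tau_ns, "punif", 0.1, 5)
  # 1% critical value of the one-sample KS statistic: 1.63 / sqrt(n)
  expect_lt(unname(ks$statistic), 1.63 / sqrt(10000))
})

test_that("degenerate array frame matches a single-pixel expectation", {
  g <- default_grid()
  sp <- array_spec(4L, 4L, peak_jitter_span_ns = 0, hot_pixel_fraction = 0,
                   dark_rate_per_bin = 0)
  f <- simulate_spad_frame(sp, tau_ns = 2, photons_per_frame = 4e4,
                           rng_seed = 5)
  total <- sum(f$counts)
  expect_lt(abs(total - 4e4), 3 * sqrt(4e4))
  # aggregated shape indistinguishable from the single-pixel law (chi-square)
  agg <- aggregate_unaligned(f)
  expected <- ground_truth_decay(2, total, default_irf_curve(), g)$counts
  keep <- expected > 5
  chi2 <- sum((agg$counts[keep] - expected[keep])^2 / expected[keep])
  dof <- sum(keep) - 1L
  expect_lt(chi2, stats::qchisq(0.999, dof))
})

test_that("hot pixels are brighter and jitter broadens the aggregate IRF", {
  sp <- array_spec(48L, 48L, peak_jitter_span_ns = 4, hot_pixel_fraction = 0.01,
                   hot_pixel_rate_multiplier = 100, dark_rate_per_bin = 1e-4)
  f <- simulate_spad_frame(sp, tau_ns = NULL, photons_per_frame = 2e5,
                           irf = irf_spec(peak_bin = 150L), rng_seed = 6)
  totals <- apply(f$counts, c(1, 2), sum)
  hot <- f$true_hot_mask
  expect_gte(mean(totals[hot]), 10 * stats::median(totals[!hot]))
  # IRF-only frame with 4 ns jitter: integrated IRF is broad
  agg <- aggregate_unaligned(f, hot_mask = f$true_hot_mask)
  expect_gt(measure_fwhm(agg), 3)
})

test_that("frame simulation validates the jitter span", {
  sp <- array_spec(4L, 4L, peak_jitter_span_ns = 20)
  expect_error(simulate_spad_frame(sp, tau_ns = 2, photons_per_frame = 100),
               "jitter")
})
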