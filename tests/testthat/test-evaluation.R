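test_that("accuracy and precision in dB match hand values", {
  expect_equal(accuracy_db(2, rep(2.2, 5)), 20)       # dtau = tau/10
  expect_equal(accuracy_db(2, rep(4, 5)), 0)          # dtau = tau
  expect_equal(accuracy_db(2, rep(2.02, 5)), 40)      # dtau = tau/100
  expect_equal(accuracy_db(2, rep(2, 5)), 100)        # sentinel cap
  expect_equal(precision_db(2, c(1.8, 2.2)), 20 * log10(2 / sd(c(1.8, 2.2))))
  expect_equal(precision_db(2, rep(2.5, 4)), 100)     # zero spread sentinel
  expect_error(accuracy_db(2, numeric(0)), "empty")
  expect_error(precision_db(2, 1.5), ">= 2")
})

test_that("dB metrics are invariant to a common rescaling", {
  set.seed(12)
  est <- rnorm(50, 2.1, 0.2)
  for (k in c(0.1, 3, 42)) {
    expect_equal(accuracy_db(2 * k, est * k), accuracy_db(2, est))
    expect_equal(precision_db(2 * k, est * k), precision_db(2, est))
  }
})

test_that("sampled precision converges to the known dispersion", {
  set.seed(13)
  est <- rnorm(1e4, 2, 0.2)
  expect_equal(precision_db(2, est), 20, tolerance = 0.2 / 20)
})

test_that("sweep scores an unbiased oracle at the sentinel in every bin", {
  # an estimator that reproduces the per-cell truth exactly (the structured
  # design lays out tau_grid blocks of `replicates` samples each)
  spec <- dataset_spec(n_samples = 10L, seed = 3L)
  tau_grid <- c(1, 2)
  truthful <- list(ORACLE = function(counts, grid) {
    rep(rep(tau_grid, each = 5), length.out = nrow(counts))
  })
  sw <- sweep_vs_counts(truthful, spec, nt_bins = cbind(500, 1000),
                        tau_grid = tau_grid, replicates = 5L)
  expect_equal(sw$mean_accuracy_db, 100)
  expect_equal(sw$mean_precision_db, 100)
  expect_equal(sw$n_samples, 10L)
})

test_that("sweep feeds identical samples to every estimator", {
  seen <- list()
  grab <- function(tag) function(counts, grid) {
    seen[[tag]] <<- counts
    rowSums(counts) * 0 + 1
  }
  sw <- sweep_vs_counts(list(a = grab("a"), b = grab("b")),
                        dataset_spec(n_samples = 10L, seed = 4L),
                        nt_bins = cbind(300, 600),
                        tau_grid = c(1, 2), replicates = 3L)
  expect_identical(seen$a, seen$b)
})

test_that("event detection thresholds intensities and reports background", {
  g <- sim_grid(50L, 0.04)
  mk <- function(total) decay_histogram(rep(total / 50, 50), g)
  frames <- lapply(c(100, 200, 150), mk)
  est <- function(counts, grid) rep(1.5, nrow(counts))
  res <- frame_event_analysis(frames, est, threshold_pc = 400)
  expect_equal(nrow(res$events), 0L)
  expect_equal(res$background_pc, 150)
  frames2 <- lapply(c(100, 500, 120, 800), mk)
  res2 <- frame_event_analysis(frames2, est, threshold_pc = 400)
  expect_equal(res2$events$frame_index, c(2L, 4L))
  expect_equal(res2$events$intensity_pc, c(500, 800))
  expect_equal(res2$background_pc, 110)
  expect_error(frame_event_analysis(list(), est), "no frames")
})

test_that("synthetic event stream is detected without false positives", {
  g <- default_grid()
  irf <- default_irf_curve()
  set.seed(41)
  n_frames <- 200L
  event_idx <- sort(sample(n_frames, 20L))
  counts <- matrix(0, n_frames, 300)
  for (i in seq_len(n_frames)) {
    base <- stats::rpois(300, 300 / 300)  # ~300 p.c. dark background
    counts[i, ] <- base
    if (i %in% event_idx) {
      nt <- stats::runif(1, 500, 1300)
      d <- ground_truth_decay(2.1, nt, irf, g)
      counts[i, ] <- counts[i, ] + pmax(d$counts + sqrt(d$counts) * rnorm(300), 0)
    }
  }
  est <- cmm_estimator(cmm_config(50L, 300L))
  res <- frame_event_analysis(counts, est, threshold_pc = 400, grid = g,
                              method = "CMM")
  expect_setequal(res$events$frame_index, event_idx)
  expect_equal(res$background_pc, mean(rowSums(counts)[-event_idx]))
})

test_that("event binning uses the conventional display widths", {
  ev <- tibble::tibble(frame_index = 1:4, intensity_pc = c(410, 415, 450, 470),
                       tau_ns = c(2.1, 2.3, 2.6, 3.4), method = "CMM")
  b <- bin_events(ev)
  expect_equal(b$lifetime$tau_mid_ns, c(2.25, 2.75, 3.25))
  expect_equal(b$lifetime$n, c(2L, 1L, 1L))
  expect_equal(b$intensity$intensity_mid_pc, c(410, 450, 470))
  expect_equal(b$intensity$n, c(2L, 1L, 1L))
})

test_that("bias summary matches the printed definition", {
  expect_equal(summarize_bias(c(2.1, 2.1), 2.1)$bias, 0)
  expect_equal(summarize_bias(rep(2.3, 3), 2.1)$bias_pct, 9.52, tolerance = 0.001)
  expect_equal(summarize_bias(rep(3.82, 3), 2.1)$bias_pct, 81.9, tolerance = 0.001)
  s <- summarize_bias(c(2.0, 2.6), 2.1)
  expect_equal(s$tau_mean_ns, 2.3)
  expect_equal(s$tau_sd_ns, sd(c(2.0, 2.6)))
})
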