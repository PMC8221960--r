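# small architecture used by the engine tests (fast, same code paths)
tiny_spec <- function() {
  network_spec(list(
    list(filters = 3L, kernel = 5L, stride = 2L, quantized = FALSE),
    list(filters = 4L, kernel = 3L, stride = 2L, quantized = TRUE),
    list(filters = 5L, kernel = 1L, stride = 1L, quantized = TRUE),
    list(filters = 3L, kernel = 1L, stride = 1L, quantized = TRUE),
    list(filters = 1L, kernel = 1L, stride = 1L, quantized = FALSE)))
}

tiny_dataset <- function(n = 256L, n_bins = 60L, seed = 17L) {
  g <- sim_grid(n_bins, 0.04)
  irf <- make_irf(irf_spec(fwhm_ns = 0.23, peak_bin = 10L), g)
  sample_dataset(dataset_spec(n_samples = n, seed = seed,
                              tau_range_ns = c(0.1, 1.5),
                              nt_range = c(200, 2000)), irf, g)
}

test_that("network spec validation enforces the architecture contract", {
  expect_error(network_spec(list(list(filters = 1))), "5 blocks")
  bad <- network_spec()$blocks
  bad[[3]]$kernel <- 3L
  expect_error(network_spec(bad), "pointwise")
  bad2 <- network_spec()$blocks
  bad2[[1]]$quantized <- TRUE
  expect_error(network_spec(bad2), "full precision")
})

test_that("default architecture parameter count is in the expected band", {
  net <- build_network()
  expect_gte(n_parameters(net), 15000)
  expect_lte(n_parameters(net), 55000)
})

test_that("with 1-bit weights every quantized layer is two-valued", {
  net <- build_network(quant = quant_scheme(1L, 4L), seed = 2)
  for (i in 2:4) {
    W_eff <- quantize_weights(net$blocks[[i]]$W, 1L)
    vals <- sort(unique(as.vector(W_eff)))
    expect_length(vals, 2L)
    expect_equal(vals, c(-1, 1) * mean(abs(net$blocks[[i]]$W)))
  }
})

test_that("analytic gradients match finite differences (STE contract)", {
  # with quantizers at the identity (full precision) the backward pass must
  # agree with numerical differentiation of the forward loss
  net <- build_network(tiny_spec(), quant_scheme("full", "full"),
                       n_bins = 40L, seed = 3)
  set.seed(4)
  X <- matrix(runif(6 * 40), 6, 40)
  y <- runif(6, 0.5, 4)
  bp <- flimq:::qcnn_backprop(net, X, y)
  loss_at <- function(n2) flimq:::qcnn_backprop(n2, X, y)$loss
  eps <- 1e-6
  worst <- 0
  for (i in 1:4) {
    for (j in sample(length(net$blocks[[i]]$W), 4)) {
      n2 <- net
      n2$blocks[[i]]$W[j] <- net$blocks[[i]]$W[j] + eps
      g_num <- (loss_at(n2) - bp$loss) / eps
      worst <- max(worst, abs(g_num - bp$grads[[i]]$dW[j]) /
                     max(abs(bp$grads[[i]]$dW[j]), 1e-6))
    }
    n2 <- net
    n2$blocks[[i]]$bn_gamma[1] <- net$blocks[[i]]$bn_gamma[1] + eps
    worst <- max(worst, abs((loss_at(n2) - bp$loss) / eps -
                              bp$grads[[i]]$dgamma[1]) /
                   max(abs(bp$grads[[i]]$dgamma[1]), 1e-6))
  }
  n2 <- net; n2$head$b <- net$head$b + eps
  worst <- max(worst, abs((loss_at(n2) - bp$loss) / eps - bp$dbh) /
                 max(abs(bp$dbh), 1e-6))
  expect_lt(worst, 1e-3)
})

test_that("full-precision output responds smoothly to its input", {
  net <- build_network(tiny_spec(), quant_scheme("full", "full"),
                       n_bins = 40L, seed = 3)
  set.seed(6)
  x <- matrix(runif(40), 1, 40)
  p0 <- flimq:::qcnn_forward(net, x)$pred
  eps <- 1e-5
  x2 <- x; x2[1, 20] <- x[1, 20] + eps
  p1 <- flimq:::qcnn_forward(net, x2)$pred
  expect_true(is.finite((p1 - p0) / eps))
  expect_lt(abs(p1 - p0), 1e-2)  # tiny input change, tiny output change
})

test_that("quantized forward activations take at most 2^k distinct levels", {
  ds <- tiny_dataset()
  net <- build_network(tiny_spec(), quant_scheme(1L, 2L), n_bins = 60L,
                       seed = 12)
  # the engine's activation quantizer and the exported one must agree
  set.seed(3)
  A <- array(runif(120, -0.2, 1.2), dim = c(2, 20, 3))
  expect_equal(quantize_activations(A, 2L),
               array(quantize_activations(as.vector(A), 2L), dim = dim(A)))
  p <- predict(net, ds$counts[1:8, , drop = FALSE])
  expect_equal(nrow(p), 8L)
})

test_that("batch prediction equals singleton predictions", {
  ds <- tiny_dataset()
  net <- build_network(tiny_spec(), quant_scheme(1L, 4L), n_bins = 60L,
                       seed = 5)
  fit <- train_qcnn(net, ds, train_config(epochs = 2L, seed = 5))
  batch <- predict(fit, ds$counts[1:10, , drop = FALSE])
  singles <- vapply(1:10, function(i) {
    predict(fit, ds$counts[i, , drop = FALSE])$tau_ns
  }, numeric(1))
  expect_equal(batch$tau_ns, singles, tolerance = 1e-12)
})

test_that("training is deterministic given seeds and makes progress", {
  ds <- tiny_dataset()
  cfg <- train_config(epochs = 8L, seed = 9)
  f1 <- train_qcnn(build_network(tiny_spec(), quant_scheme(1L, 4L),
                                 n_bins = 60L, seed = 9), ds, cfg)
  f2 <- train_qcnn(build_network(tiny_spec(), quant_scheme(1L, 4L),
                                 n_bins = 60L, seed = 9), ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history$val_mse[8], f1$history$val_mse[1])
})

test_that("prediction validates input length and flags weak signals", {
  ds <- tiny_dataset()
  net <- build_network(tiny_spec(), quant_scheme(1L, 4L), n_bins = 60L,
                       seed = 5)
  expect_error(predict(net, matrix(0.5, 1, 30)), "does not match")
  strong <- ds$counts[1, , drop = FALSE]
  weak <- matrix(0.05, 1, 60)
  p <- predict(net, rbind(strong, weak))
  expect_equal(p$flag, c("ok", "low_signal"))
  expect_true(all(p$tau_ns >= 0))
})

test_that("tidy/glance report loss curves and configuration", {
  ds <- tiny_dataset()
  fit <- train_qcnn(build_network(tiny_spec(), quant_scheme(1L, 4L),
                                  n_bins = 60L, seed = 4),
                    ds, train_config(epochs = 3L, seed = 4))
  td <- tidy(fit)
  expect_named(td, c("epoch", "set", "mse"))
  expect_equal(nrow(td), 6L)
  gl <- glance(fit)
  expect_equal(gl$epochs, 3L)
  expect_equal(gl$w_bits, "1")
  expect_true(gl$best_val_mse <= gl$final_val_mse + 1e-12 ||
                gl$best_val_mse <= max(fit$history$val_mse))
})
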