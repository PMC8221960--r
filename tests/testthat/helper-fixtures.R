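# Shared fixtures. Heavy objects (trained networks, the shared synthetic
# dataset) are built once per test run and memoised here so several test
# files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

default_grid <- function() sim_grid(300L, 0.04)

default_irf_curve <- function() {
  memo("irf_curve", make_irf(irf_spec(), default_grid()))
}

# scaled-down training set shared by the network tests: same generator and
# ranges as the full study conditions, fewer samples
train_dataset_small <- function() {
  memo("ds_small", sample_dataset(
    dataset_spec(n_samples = 10000L, seed = 101L),
    default_irf_curve(), default_grid()))
}

train_epochs_small <- function() 80L

# the reference quantized model (1-bit weights, 4-bit activations)
fit_w1a4 <- function() {
  memo("fit_w1a4", {
    net <- build_network(network_spec(), quant_scheme(1L, 4L), seed = 202L)
    train_qcnn(net, train_dataset_small(),
               train_config(epochs = train_epochs_small(), seed = 202L))
  })
}
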