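# flimq

Fluorescence lifetime estimation for SPAD-array TCSPC data, with a
quantized neural-network estimator.

## The problem

Time-correlated single-photon counting (TCSPC) builds a histogram of photon
arrival times after a laser pulse; the fluorescence lifetime τ is the time
constant of the histogram's exponential tail, blurred by the instrument
response function (IRF). SPAD (single-photon avalanche diode) arrays make
TCSPC fast — every pixel timestamps photons in parallel, and one exposure
frame of the whole array yields one decay — but the resulting decays are
photon-starved (hundreds of counts) and noisy, and each pixel's timing
chain responds with its own delay, so the array must be calibrated before
its pixels can be summed into a single "megapixel" histogram.

flimq implements that stack for people developing or evaluating lifetime
instrumentation and analysis:

* **Simulation** — single-exponential decays `y = N_T · (IRF ∗ e^(−t/τ))`
  on a 300 × 0.04 ns grid with shot noise and additive Gaussian noise
  (`Y_i = y_i + √y_i·ε_i + η_i`, clamped at 0), and full SPAD-array frames
  with per-pixel IRF peak jitter, hot pixels and dark counts.
* **Calibration** — per-pixel peak estimation, hot-pixel masking
  (k × median rule), integer-shift alignment and aggregation, leading-bin
  background subtraction, FWHM measurement.
* **Estimators** —
  * CMM, the hardware center-of-mass method: normalized window centroid
    `c = (Σ i·D_i/N_T − 1/2)/M`, corrected for window truncation through
    the inverse of `g(r) = r − 1/(e^{1/r} − 1)` (Ω lookup table), with
    optional IRF-delay subtraction;
  * NLSD, Levenberg–Marquardt fitting of the IRF-convolved model with a
    rectified-mean correction for the zero-clamped noise;
  * QCNN, a five-block 1-D convolutional regressor whose three middle
    blocks carry DoReFa-quantized weights and activations (defaults: 1-bit
    weights, 4-bit activations), trained with the straight-through
    estimator. The training engine (im2col convolutions, fused
    batch-norm/ReLU, Adam) is built into the package in C++/BLAS — no
    external deep-learning framework.
* **Evaluation** — accuracy `20·log10(τ/|Δτ|)` and precision
  `20·log10(τ/σ_τ)` in dB, estimator sweeps versus photon count, and
  per-frame event detection for flowing-particle streams (intensity
  threshold over a dark background).

## Worked example

Simulate a photon-starved decay and estimate its lifetime three ways:

```r
library(flimq)

grid <- sim_grid(300, 0.04)
irf  <- make_irf(irf_spec(fwhm_ns = 0.23, peak_bin = 50), grid)

truth <- ground_truth_decay(tau_ns = 2, n_total = 800, irf, grid)
noisy <- add_noise(truth, noise_spec(sigma = 2), rng_seed = 7)

cmm_lifetime(noisy, cmm_config(50, 300),
             irf_hist = decay_histogram(irf * 1e4, grid))
#> # A tibble: 1 × 5
#>   tau_ns method raw_centroid_ns irf_correction_ns status
#>    <dbl> <chr>            <dbl>             <dbl> <chr>
#> 1   2.80 CMM               2.57            0.0860 ok

nlsd_fit(noisy, irf)
#> <nlsd_fit> tau = 1.892 ns, A = 787.4, b = 0.2621 [ok]
```

The centroid method overestimates (2.80 ns vs the true 2 ns): at 800
photons the additive background it does not model drags the window
centroid toward the window middle — its documented noise sensitivity
(subtracting the background first with `subtract_background()` largely
removes the bias). The NLSD fit (1.89 ns) models the background and the
zero-clamped noise explicitly and lands within photon-noise scatter of
the truth, recovering the amplitude ≈ 787 of the 800 expected photons.

Train the quantized network on the standard synthetic dataset and compare
it with CMM at low photon counts:

```r
ds  <- sample_dataset(dataset_spec(n_samples = 50000, seed = 1), irf, grid)
net <- build_network(network_spec(), quant_scheme(w_bits = 1, a_bits = 4))
fit <- train_qcnn(net, ds, train_config(epochs = 100, seed = 1))
glance(fit)           # plateau validation MSE ~0.05 ns² (near the
                      # information floor of this noise model; see the
                      # methods vignette)
autoplot(fit)         # train/validation loss curves

sw <- sweep_vs_counts(
  list(CMM  = cmm_estimator(cmm_config(50, 300),
                            decay_histogram(irf * 1e4, grid)),
       QCNN = qcnn_estimator(fit)),
  test_spec = dataset_spec(seed = 2),
  nt_bins = cbind(c(300, 9000), c(500, 10000)), grid = grid, irf = irf)
autoplot(sw)
```

In that sweep the QCNN's mean accuracy on 300–500-count decays matches or
exceeds CMM's on 9,000–10,000-count decays — the network's robustness to
noise is worth more than an order of magnitude in photons to the classical
estimator.

A thin command-line interface over the same functions ships in
`inst/cli/flimq.R` (`simulate`, `calibrate`, `train`, `ablate`, `estimate`,
`evaluate`), and `run_pipeline()` drives the whole chain from a YAML
config.

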