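#' Specification of a synthetic training/test dataset
#'
#' Each sample is a single-exponential decay drawn with lifetime
#' `tau ~ U(tau_range_ns)`, total count `N_T ~ U(nt_range)` and additive
#' noise level `sigma ~ U(1, N_T / 300)`, then passed through the measured
#' decay noise model (see [add_noise()]). The defaults match a training set
#' of 50,000 samples with 20% held out for validation, lifetimes 0.1–5 ns and
#' total counts 100–10,000.
#'
#' @param n_samples Number of decays (default 50000).
#' @param val_fraction Fraction held out for validation, in `[0, 1)`
#'   (default 0.2).
#' @param tau_range_ns Lifetime range in ns (default `c(0.1, 5)`).
#' @param nt_range Total photon count range (default `c(100, 1e4)`).
#' @param sigma_max_divisor `sigma` is drawn uniformly on
#'   `[1, N_T / sigma_max_divisor]` (default 300); the ground-truth `N_T`
#'   (before noise) sets the upper bound.
#' @param seed Integer RNG seed; sampling is deterministic given the spec.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_samples = 50000L, val_fraction = 0.2,
                         tau_range_ns = c(0.1, 5), nt_range = c(100, 1e4),
                         sigma_max_divisor = 300, seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  if (!is.finite(val_fraction) || val_fraction < 0 || val_fraction >= 1) {
    stop("`val_fraction` must be in [0, 1)", call. = FALSE)
  }
  check_range <- function(r, nm) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      stop(sprintf("`%s` must be an ordered pair (low < high)", nm), call. = FALSE)
    }
  }
  check_range(tau_range_ns, "tau_range_ns")
  check_range(nt_range, "nt_range")
  structure(list(n_samples = n_samples, val_fraction = val_fraction,
                 tau_range_ns = tau_range_ns, nt_range = nt_range,
                 sigma_max_divisor = sigma_max_divisor,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Sample a synthetic decay dataset
#'
#' Draws `n_samples` noisy decays per the [dataset_spec()]: for each sample a
#' lifetime, total count and noise level are drawn, the expected decay is
#' computed with [ground_truth_decay()], and measurement noise is applied
#' with [add_noise()]. Samples are split into train/validation at the
#' specified fraction. Fully deterministic given `spec$seed`.
#'
#' @param spec A [dataset_spec()].
#' @param irf IRF curve (from [make_irf()]).
#' @param grid A [sim_grid()].
#' @return A list of class `decay_dataset`:
#'   * `counts`: `n_samples x n_bins` matrix of noisy counts;
#'   * `meta`: tibble with `sample_id`, `tau_ns`, `n_total`, `sigma`, `split`
#'     (`"train"`/`"validation"`);
#'   * `grid`, `spec`.
#' @examples
#' g <- sim_grid()
#' ds <- sample_dataset(dataset_spec(n_samples = 10), make_irf(irf_spec(), g), g)
#' table(ds$meta$split)
#' @export
sample_dataset <- function(spec, irf, grid = sim_grid()) {
  stopifnot(inherits(spec, "dataset_spec"), inherits(grid, "sim_grid"))
  set.seed(spec$seed)
  n <- spec$n_samples
  tau <- stats::runif(n, spec$tau_range_ns[1], spec$tau_range_ns[2])
  nt <- stats::runif(n, spec$nt_range[1], spec$nt_range[2])
  sigma <- stats::runif(n, pmin(1, nt / spec$sigma_max_divisor),
                        nt / spec$sigma_max_divisor)

  nb <- grid$n_bins
  irf_v <- as.numeric(irf)
  counts <- matrix(0, nrow = n, ncol = nb)
  for (i in seq_len(n)) {
    y <- decay_conv(irf_v, tau[i], grid)
    y <- y / sum(y) * nt[i]
    noisy <- y + sqrt(y) * stats::rnorm(nb) + stats::rnorm(nb, sd = sigma[i])
    counts[i, ] <- pmax(noisy, 0)
  }

  n_val <- round(spec$val_fraction * n)
  split <- rep("train", n)
  if (n_val > 0) {
    split[sample.int(n, n_val)] <- "validation"
  }
  meta <- tibble::tibble(sample_id = seq_len(n), tau_ns = tau, n_total = nt,
                         sigma = sigma, split = split)
  structure(list(counts = counts, meta = meta, grid = grid, spec = spec),
            class = "decay_dataset")
}

#' @export
print.decay_dataset <- function(x, ...) {
  cat(sprintf("<decay_dataset> %d samples x %d bins (%d train / %d validation)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$meta$split == "train"), sum(x$meta$split == "validation")))
  invisible(x)
}

#' @export
as_tibble.decay_dataset <- function(x, ...) {
  out <- x$meta
  out$counts <- lapply(seq_len(nrow(x$counts)), function(i) x$counts[i, ])
  out
}
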