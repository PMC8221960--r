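#' TCSPC decay histogram
#'
#' The universal currency between flimq modules: photon counts per time bin
#' on a [sim_grid()]. Counts are non-negative reals — expected (noise-free)
#' decays are continuous, measured ones may be integer.
#'
#' @param counts Numeric vector of non-negative counts, one per bin.
#' @param grid A [sim_grid()] whose `n_bins` matches `length(counts)`.
#' @return An object of class `decay_histogram` with fields `counts`, `grid`
#'   and `total_counts`.
#' @examples
#' h <- decay_histogram(rep(1, 300), sim_grid())
#' h$total_counts
#' @export
decay_histogram <- function(counts, grid = sim_grid(length(counts))) {
  stopifnot(inherits(grid, "sim_grid"))
  counts <- as.numeric(counts)
  if (length(counts) != grid$n_bins) {
    stop(sprintf("length(counts) = %d but grid has %d bins",
                 length(counts), grid$n_bins), call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  structure(list(counts = counts, grid = grid, total_counts = sum(counts)),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins x %.4g ns, %.6g total counts\n",
              x$grid$n_bins, x$grid$bin_width_ns, x$total_counts))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.decay_histogram <- function(x, ...) {
  tibble::tibble(
    bin_index = seq_len(x$grid$n_bins),
    time_ns = bin_times_ns(x$grid),
    counts = x$counts
  )
}

#' Noise specification for measured decays
#'
#' Measured decays are modeled as the ground truth plus shot (Poisson-like)
#' noise and additive Gaussian noise of standard deviation `sigma`:
#' `Y_i = y_i + sqrt(y_i) * N(0,1) + N(0, sigma)`. The shot-noise term uses
#' the normal approximation to Poisson counting noise (variance equal to the
#' mean), hence the square root.
#'
#' @param sigma Standard deviation of the additive Gaussian term, in counts.
#' @param poisson_enabled Include the shot-noise term? Default `TRUE`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, poisson_enabled = TRUE) {
  if (!is.finite(sigma) || sigma < 0) {
    stop("`sigma` must be a non-negative number", call. = FALSE)
  }
  structure(list(sigma = sigma, poisson_enabled = isTRUE(poisson_enabled)),
            class = "noise_spec")
}

#' Noise-free single-exponential decay convolved with an IRF
#'
#' The expected decay is the linear (zero-padded) convolution of the IRF
#' curve with the exponential kernel `exp(-t/tau)`, truncated to the
#' measurement window and renormalized so the counts sum to exactly
#' `n_total`. Decay mass falling beyond the last bin is discarded before
#' renormalization, so the total over the window is exact.
#'
#' @param tau_ns Fluorescence lifetime in ns (> 0).
#' @param n_total Total expected photon count over the window (> 0).
#' @param irf IRF curve from [make_irf()] or [delta_irf()] (length `n_bins`).
#' @param grid A [sim_grid()].
#' @return A [decay_histogram()] whose counts sum to `n_total`.
#' @examples
#' g <- sim_grid()
#' d <- ground_truth_decay(2, 1000, make_irf(irf_spec(), g), g)
#' d$total_counts
#' @export
ground_truth_decay <- function(tau_ns, n_total, irf, grid = sim_grid()) {
  stopifnot(inherits(grid, "sim_grid"))
  if (!is.finite(tau_ns) || tau_ns <= 0) {
    stop("`tau_ns` must be positive", call. = FALSE)
  }
  if (!is.finite(n_total) || n_total <= 0) {
    stop("`n_total` must be positive", call. = FALSE)
  }
  n <- grid$n_bins
  if (length(irf) != n) stop("IRF length does not match the grid", call. = FALSE)
  y <- decay_conv(as.numeric(irf), tau_ns, grid)
  y <- y / sum(y) * n_total
  decay_histogram(y, grid)
}

# Linear (zero-padded) convolution of the IRF with the exponential kernel
# exp(-(m-1)h/tau), truncated to the window. The convolution satisfies the
# exact recurrence y_i = d * y_{i-1} + irf_i with d = exp(-h/tau), evaluated
# in C by stats::filter; overflow-free for any tau and O(n).
decay_conv <- function(irf, tau_ns, grid) {
  d <- exp(-grid$bin_width_ns / tau_ns)
  as.numeric(stats::filter(irf, filter = d, method = "recursive"))
}

#' Add measurement noise to a decay
#'
#' Applies the measured-decay model
#' `Y_i = y_i + sqrt(y_i) * eps_i + eta_i`, with `eps_i ~ N(0,1)` modeling
#' shot noise (normal approximation to Poisson, variance = mean) and
#' `eta_i ~ N(0, sigma)` modeling background/electronics noise, independently
#' per bin. Negative results are clamped at 0; counts stay real-valued unless
#' `round_counts = TRUE`.
#'
#' @param clean A [decay_histogram()] of expected counts.
#' @param noise A [noise_spec()].
#' @param rng_seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @param round_counts Round the noisy counts to integers (for estimator
#'   stress tests)? Default `FALSE`.
#' @return A [decay_histogram()] of noisy counts.
#' @export
add_noise <- function(clean, noise = noise_spec(), rng_seed = NULL,
                      round_counts = FALSE) {
  stopifnot(inherits(clean, "decay_histogram"), inherits(noise, "noise_spec"))
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  y <- clean$counts
  out <- y
  if (noise$poisson_enabled) {
    out <- out + sqrt(y) * stats::rnorm(length(y))
  }
  if (noise$sigma > 0) {
    out <- out + stats::rnorm(length(y), sd = noise$sigma)
  }
  out <- pmax(out, 0)
  if (isTRUE(round_counts)) out <- round(out)
  decay_histogram(out, clean$grid)
}

#' Centroid time of a histogram
#'
#' First moment of the counts using the bin-center convention
#' `t_i = (i - 1/2) h`, in ns.
#'
#' @param hist A [decay_histogram()].
#' @return Centroid time in ns.
#' @export
centroid_time_ns <- function(hist) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (hist$total_counts <= 0) stop("histogram has no counts", call. = FALSE)
  sum(bin_times_ns(hist$grid) * hist$counts) / hist$total_counts
}
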