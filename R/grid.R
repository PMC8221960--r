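#' Time-bin grid of a TCSPC measurement
#'
#' Describes the discretization of the photon-arrival time axis: the number of
#' time-to-digital-converter (TDC) bins and their width. All histograms,
#' instrument response functions and decays in flimq live on such a grid.
#' Bin indices are 1-based everywhere in the user-facing API; the time
#' assigned to bin `i` is its center, `(i - 1/2) * bin_width_ns`.
#'
#' @param n_bins Number of TDC time bins (default 300).
#' @param bin_width_ns Bin width in nanoseconds (default 0.04).
#'
#' @return An object of class `sim_grid` with fields `n_bins` and
#'   `bin_width_ns`.
#' @examples
#' g <- sim_grid()
#' grid_window_ns(g) # 12 ns
#' @export
sim_grid <- function(n_bins = 300L, bin_width_ns = 0.04) {
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 2L) {
    stop("`n_bins` must be a single integer >= 2", call. = FALSE)
  }
  if (length(bin_width_ns) != 1L || !is.finite(bin_width_ns) || bin_width_ns <= 0) {
    stop("`bin_width_ns` must be a single positive number", call. = FALSE)
  }
  structure(list(n_bins = n_bins, bin_width_ns = bin_width_ns),
            class = "sim_grid")
}

#' @rdname sim_grid
#' @param grid A `sim_grid`.
#' @export
grid_window_ns <- function(grid) {
  stopifnot(inherits(grid, "sim_grid"))
  grid$n_bins * grid$bin_width_ns
}

#' Bin-center times of a grid
#'
#' @param grid A [sim_grid()].
#' @return Numeric vector of length `n_bins`: `(i - 1/2) * bin_width_ns`.
#' @export
bin_times_ns <- function(grid) {
  stopifnot(inherits(grid, "sim_grid"))
  (seq_len(grid$n_bins) - 0.5) * grid$bin_width_ns
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d bins x %.4g ns (window %.4g ns)\n",
              x$n_bins, x$bin_width_ns, grid_window_ns(x)))
  invisible(x)
}

#' Parametric Gaussian instrument response function
#'
#' The instrument response function (IRF) is the temporal blur of the photon
#' timing chain (laser pulse, detector jitter, TDC). It is modeled as a
#' Gaussian characterized by its full width at half maximum (FWHM) and the
#' bin index of its peak.
#'
#' @param fwhm_ns Full width at half maximum in ns (default 0.23).
#' @param peak_bin 1-based bin index of the IRF peak (default 50).
#' @return An object of class `irf_spec`.
#' @examples
#' irf_spec()
#' @export
irf_spec <- function(fwhm_ns = 0.23, peak_bin = 50L) {
  if (!is.finite(fwhm_ns) || fwhm_ns <= 0) {
    stop("`fwhm_ns` must be positive", call. = FALSE)
  }
  peak_bin <- as.integer(peak_bin)
  if (is.na(peak_bin) || peak_bin < 1L) {
    stop("`peak_bin` must be a positive integer", call. = FALSE)
  }
  structure(list(fwhm_ns = fwhm_ns, peak_bin = peak_bin), class = "irf_spec")
}

#' @export
print.irf_spec <- function(x, ...) {
  cat(sprintf("<irf_spec> Gaussian, FWHM %.3g ns, peak at bin %d\n",
              x$fwhm_ns, x$peak_bin))
  invisible(x)
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Discretize a Gaussian IRF onto a time grid
#'
#' Evaluates the Gaussian density at bin centers and normalizes so the curve
#' sums to exactly 1. If the peak sits so close to the window edge that more
#' than 1% of the Gaussian mass is truncated, the returned curve carries a
#' `truncated` attribute set to `TRUE` and a warning is emitted.
#'
#' @param spec An [irf_spec()].
#' @param grid A [sim_grid()]; `peak_bin` must lie inside it.
#' @return Numeric vector of length `grid$n_bins` summing to 1, with
#'   attributes `peak_bin`, `fwhm_ns` and `truncated`.
#' @examples
#' curve <- make_irf(irf_spec(), sim_grid())
#' which.max(curve) # 50
#' @export
make_irf <- function(spec = irf_spec(), grid = sim_grid()) {
  stopifnot(inherits(spec, "irf_spec"), inherits(grid, "sim_grid"))
  if (spec$peak_bin > grid$n_bins) {
    stop("IRF `peak_bin` lies outside the grid", call. = FALSE)
  }
  sigma <- fwhm_to_sigma(spec$fwhm_ns)
  t <- bin_times_ns(grid)
  mu <- (spec$peak_bin - 0.5) * grid$bin_width_ns
  dens <- stats::dnorm(t, mean = mu, sd = sigma)
  # mass retained inside the window, per the continuous Gaussian
  lo <- stats::pnorm(0, mean = mu, sd = sigma)
  hi <- stats::pnorm(grid_window_ns(grid), mean = mu, sd = sigma, lower.tail = FALSE)
  truncated <- (lo + hi) > 0.01
  if (truncated) {
    warning("IRF peak too close to the window edge: >1% of Gaussian mass truncated",
            call. = FALSE)
  }
  curve <- dens / sum(dens)
  attr(curve, "peak_bin") <- spec$peak_bin
  attr(curve, "fwhm_ns") <- spec$fwhm_ns
  attr(curve, "truncated") <- truncated
  curve
}

#' A delta (single-bin) IRF
#'
#' Convenience for an idealized instrument with no temporal blur: all IRF
#' mass in one bin. Useful for validating estimators against closed-form
#' truncated-exponential results.
#'
#' @param peak_bin Bin holding the unit mass.
#' @param grid A [sim_grid()].
#' @return Numeric vector of length `n_bins` with a single 1.
#' @export
delta_irf <- function(peak_bin = 1L, grid = sim_grid()) {
  stopifnot(inherits(grid, "sim_grid"))
  peak_bin <- as.integer(peak_bin)
  if (peak_bin < 1L || peak_bin > grid$n_bins) {
    stop("`peak_bin` outside the grid", call. = FALSE)
  }
  curve <- numeric(grid$n_bins)
  curve[peak_bin] <- 1
  attr(curve, "peak_bin") <- peak_bin
  attr(curve, "truncated") <- FALSE
  curve
}
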