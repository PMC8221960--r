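#' Truncation-bias lookup table for the center-of-mass method
#'
#' For a single-exponential decay observed over a finite window of length
#' `T = M h`, the normalized centroid (first moment divided by the window
#' length, with time measured from the window start) is
#' `c = g(r) = r - 1 / (exp(1/r) - 1)` where `r = tau / T`. The
#' center-of-mass method measures `c` and needs the inverse `Omega(c) = r`
#' — the bias correction that undoes window truncation. This function
#' tabulates `g` on a log-spaced grid of `r` and exposes the inverse by
#' monotone linear interpolation, falling back to root finding for centroids
#' beyond the tabulated range (but below the theoretical supremum 1/2, the
#' centroid of a uniform distribution).
#'
#' @param n_points Number of LUT knots (default 8192, giving round-trip
#'   error below 1e-6 over the working range).
#' @param r_max Largest tabulated normalized lifetime `tau / T` (default 10).
#' @return An object of class `omega_lut`: callable via [omega_correct()].
#' @examples
#' lut <- build_omega_lut()
#' omega_correct(lut, 0.1932) # about 0.2
#' @export
build_omega_lut <- function(n_points = 8192L, r_max = 10) {
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  if (r_max <= 0) stop("`r_max` must be positive", call. = FALSE)
  r <- exp(seq(log(1e-4), log(r_max), length.out = n_points))
  cgrid <- centroid_of_truncated_exp(r)
  structure(list(r = r, c = cgrid, r_max = r_max), class = "omega_lut")
}

#' Normalized centroid of a window-truncated exponential
#'
#' `g(r) = r - 1/(exp(1/r) - 1)` with `r = tau / T`: the first moment (as a
#' fraction of the window length) of `exp(-t/tau)` restricted to `[0, T]`.
#' Strictly increasing, with `g(r) -> r` as `r -> 0` and `g(r) -> 1/2` as
#' `r -> Inf`.
#'
#' @param r Normalized lifetime(s), positive.
#' @return Normalized centroid(s) in (0, 1/2).
#' @export
centroid_of_truncated_exp <- function(r) {
  stopifnot(all(r > 0))
  # expm1 overflows to Inf for tiny r; 1/Inf = 0 gives the exact limit g = r
  r - 1 / expm1(1 / r)
}

#' Invert the centroid relation (apply the Omega correction)
#'
#' Maps a measured normalized centroid `c` back to the normalized lifetime
#' `r = tau / T` using the LUT, with root-finding refinement for queries
#' beyond the tabulated range. Centroids at or above 1/2 are out of domain:
#' no truncated exponential has its center of mass past the window middle
#' (this signals a lifetime far exceeding the window or un-subtracted
#' background).
#'
#' @param lut An [build_omega_lut()] result.
#' @param c_val Normalized centroid(s) in (0, 1/2).
#' @return Normalized lifetime(s) `r`.
#' @export
omega_correct <- function(lut, c_val) {
  stopifnot(inherits(lut, "omega_lut"))
  if (any(!is.finite(c_val)) || any(c_val <= 0)) {
    stop("centroid must be positive and finite", call. = FALSE)
  }
  if (any(c_val >= 0.5)) {
    stop("centroid >= 1/2 is out of the correction domain ",
         "(lifetime too long for the window or un-subtracted background)",
         call. = FALSE)
  }
  out <- numeric(length(c_val))
  below <- c_val < lut$c[1]
  # below the table the bias vanishes: g(r) ~ r
  out[below] <- c_val[below]
  inside <- !below & c_val <= lut$c[length(lut$c)]
  if (any(inside)) {
    out[inside] <- stats::approx(lut$c, lut$r, xout = c_val[inside],
                                 ties = "ordered")$y
  }
  beyond <- !below & !inside
  for (i in which(beyond)) {
    out[i] <- stats::uniroot(function(r) centroid_of_truncated_exp(r) - c_val[i],
                             lower = lut$r_max, upper = 1e8, tol = 1e-10)$root
  }
  out
}

#' Configuration of the center-of-mass lifetime estimator
#'
#' @param window_start_bin First bin of the measurement window, normally the
#'   IRF peak (default 50).
#' @param window_end_bin Last bin of the window (default 300).
#' @param lut An [build_omega_lut()] (built with defaults when omitted).
#' @return An object of class `cmm_config`.
#' @export
cmm_config <- function(window_start_bin = 50L, window_end_bin = 300L,
                       lut = build_omega_lut()) {
  window_start_bin <- as.integer(window_start_bin)
  window_end_bin <- as.integer(window_end_bin)
  if (window_start_bin < 1L || window_start_bin >= window_end_bin) {
    stop("require 1 <= window_start_bin < window_end_bin", call. = FALSE)
  }
  stopifnot(inherits(lut, "omega_lut"))
  structure(list(window_start_bin = window_start_bin,
                 window_end_bin = window_end_bin, lut = lut),
            class = "cmm_config")
}

#' Center-of-mass (CMM) lifetime estimate
#'
#' The hardware-friendly estimator: over the measurement window of `M` bins
#' the normalized centroid is computed with the bin-center convention,
#' `c = (sum_i i D_i / N_T - 1/2) / M` (`i` = 1-based bin index within the
#' window), and the lifetime is `tau = Omega(c) * M * h` where `Omega`
#' undoes the window-truncation bias. When an IRF histogram is supplied the
#' calibrated estimate `tau - tau_IRF` is returned, `tau_IRF` being the same
#' estimator applied to the IRF (removing the IRF's own centroid delay).
#'
#' @param hist A [decay_histogram()].
#' @param config A [cmm_config()].
#' @param irf_hist Optional [decay_histogram()] of the measured IRF for
#'   calibration.
#' @return One-row tibble: `tau_ns`, `method = "CMM"`, `raw_centroid_ns`
#'   (centroid time within the window), `irf_correction_ns`, `status`.
#' @examples
#' g <- sim_grid(250, 0.04)
#' d <- ground_truth_decay(2, 1e4, delta_irf(1, g), g)
#' cmm_lifetime(d, cmm_config(1, 250))$tau_ns # ~2
#' @export
cmm_lifetime <- function(hist, config = cmm_config(), irf_hist = NULL) {
  stopifnot(inherits(hist, "decay_histogram"), inherits(config, "cmm_config"))
  if (config$window_end_bin > hist$grid$n_bins) {
    stop("CMM window extends past the histogram", call. = FALSE)
  }
  tau <- cmm_tau_raw(hist, config)
  corr <- 0
  if (!is.null(irf_hist)) {
    stopifnot(inherits(irf_hist, "decay_histogram"))
    corr <- cmm_tau_raw(irf_hist, config)
    tau <- tau - corr
  }
  tibble::tibble(tau_ns = tau, method = "CMM",
                 raw_centroid_ns = cmm_centroid_ns(hist, config),
                 irf_correction_ns = corr, status = "ok")
}

cmm_centroid_ns <- function(hist, config) {
  D <- hist$counts[config$window_start_bin:config$window_end_bin]
  nt <- sum(D)
  if (nt <= 0) stop("no counts inside the CMM window", call. = FALSE)
  M <- length(D)
  (sum(seq_len(M) * D) / nt - 0.5) * hist$grid$bin_width_ns
}

cmm_tau_raw <- function(hist, config) {
  D <- hist$counts[config$window_start_bin:config$window_end_bin]
  nt <- sum(D)
  if (nt <= 0) stop("no counts inside the CMM window", call. = FALSE)
  M <- length(D)
  cc <- (sum(seq_len(M) * D) / nt - 0.5) / M
  r <- omega_correct(config$lut, cc)
  r * M * hist$grid$bin_width_ns
}

#' Vectorized CMM over a matrix of histograms
#'
#' Applies the CMM estimator row-wise to a samples-by-bins count matrix,
#' returning `NA` (status `"failed"`) for rows whose centroid is out of the
#' correction domain instead of erroring.
#'
#' @param counts Numeric matrix, samples in rows, bins in columns.
#' @param grid The common [sim_grid()].
#' @param config A [cmm_config()].
#' @param irf_hist Optional IRF [decay_histogram()] for calibration.
#' @return Tibble with `sample_id`, `tau_ns`, `method`, `status`.
#' @export
cmm_lifetime_matrix <- function(counts, grid, config = cmm_config(),
                                irf_hist = NULL) {
  stopifnot(is.matrix(counts), inherits(grid, "sim_grid"))
  w <- config$window_start_bin:config$window_end_bin
  M <- length(w)
  D <- counts[, w, drop = FALSE]
  nt <- rowSums(D)
  cc <- (as.vector(D %*% seq_len(M)) / nt - 0.5) / M
  ok <- is.finite(cc) & cc > 0 & cc < 0.5 & nt > 0
  tau <- rep(NA_real_, nrow(counts))
  if (any(ok)) {
    tau[ok] <- omega_correct(config$lut, cc[ok]) * M * grid$bin_width_ns
  }
  if (!is.null(irf_hist)) {
    tau <- tau - cmm_tau_raw(irf_hist, config)
  }
  tibble::tibble(sample_id = seq_len(nrow(counts)), tau_ns = tau,
                 method = "CMM", status = ifelse(ok, "ok", "failed"))
}
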