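#' SPAD pixel-array specification
#'
#' Describes the simulated single-photon avalanche diode (SPAD) array and its
#' imperfections: per-pixel IRF peak jitter (each pixel's timing chain
#' responds with a slightly different delay), hot pixels (abnormally high
#' dark-count rate) and a uniform dark-count floor.
#'
#' Hot pixels are modeled as dark-count dominated: a hot pixel's total rate
#' is `hot_pixel_rate_multiplier` times the mean per-pixel photon rate,
#' spread uniformly over the time bins.
#'
#' The default `dark_rate_per_bin` is chosen so an all-dark 192 x 128 frame
#' totals about 300 counts, matching a dark-count background of roughly
#' 300 photon counts per 1 ms exposure.
#'
#' @param n_rows,n_cols Array geometry (defaults 192 x 128).
#' @param peak_jitter_span_ns Full span of the uniform per-pixel IRF peak
#'   jitter, in ns (default 4; offsets are drawn on +/- span/2).
#' @param hot_pixel_fraction Fraction of hot pixels (default 0.01).
#' @param hot_pixel_rate_multiplier Rate multiplier for hot pixels
#'   (default 100).
#' @param dark_rate_per_bin Expected dark counts per pixel per bin per frame.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(n_rows = 192L, n_cols = 128L,
                       peak_jitter_span_ns = 4,
                       hot_pixel_fraction = 0.01,
                       hot_pixel_rate_multiplier = 100,
                       dark_rate_per_bin = 300 / (192 * 128 * 300)) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("array dimensions must be positive", call. = FALSE)
  if (peak_jitter_span_ns < 0) stop("`peak_jitter_span_ns` must be >= 0", call. = FALSE)
  if (hot_pixel_fraction < 0 || hot_pixel_fraction >= 1) {
    stop("`hot_pixel_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (hot_pixel_fraction > 0 && hot_pixel_rate_multiplier <= 1) {
    stop("`hot_pixel_rate_multiplier` must exceed 1", call. = FALSE)
  }
  if (dark_rate_per_bin < 0) stop("`dark_rate_per_bin` must be >= 0", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 peak_jitter_span_ns = peak_jitter_span_ns,
                 hot_pixel_fraction = hot_pixel_fraction,
                 hot_pixel_rate_multiplier = hot_pixel_rate_multiplier,
                 dark_rate_per_bin = dark_rate_per_bin),
            class = "array_spec")
}

#' Simulate one exposure frame of a SPAD array
#'
#' Each pixel observes the same temporal profile — an IRF-convolved
#' exponential decay (or the bare IRF when `tau_ns = NULL`, emulating an
#' IRF-only scattering measurement) — shifted by that pixel's integer peak
#' offset, drawn uniformly over +/- half the jitter span. The total photon
#' budget is Poisson-distributed and allocated uniformly across normal
#' pixels; hot pixels instead emit dark-like counts at
#' `hot_pixel_rate_multiplier` times the mean pixel rate, uniform over bins.
#' A uniform dark-count rate is added to every pixel and bin. Per-pixel
#' per-bin counts are drawn as independent Poissons, which is exactly
#' equivalent to a Poisson total budget multinomially thinned over pixels
#' and bins.
#'
#' Ground-truth peak offsets and the hot-pixel mask are recorded on the
#' returned object for calibration benchmarking.
#'
#' @param array An [array_spec()].
#' @param tau_ns Fluorescence lifetime in ns, or `NULL` for an IRF-only
#'   frame.
#' @param photons_per_frame Expected total signal photons in the frame.
#' @param irf An [irf_spec()] (the per-pixel IRF before jitter).
#' @param grid A [sim_grid()].
#' @param rng_seed Optional integer seed.
#' @param peak_offsets,hot_mask Optional matrices pinning the per-pixel
#'   offsets and hot-pixel labels. Offsets and hot pixels are properties of
#'   the device, not of one exposure, so when simulating several frames of
#'   the same array pass the first frame's `true_peak_offsets` and
#'   `true_hot_mask` to the later calls.
#' @return An object of class `spad_frame`: list with `counts`
#'   (`n_rows x n_cols x n_bins` array), `true_peak_offsets`,
#'   `true_hot_mask`, `grid`, `array`.
#' @examples
#' f <- simulate_spad_frame(array_spec(8, 8, peak_jitter_span_ns = 0,
#'                                     hot_pixel_fraction = 0,
#'                                     dark_rate_per_bin = 0),
#'                          tau_ns = 2, photons_per_frame = 1e4,
#'                          rng_seed = 1)
#' sum(f$counts)
#' @export
simulate_spad_frame <- function(array = array_spec(), tau_ns = NULL,
                                photons_per_frame = 1e5,
                                irf = irf_spec(), grid = sim_grid(),
                                rng_seed = NULL, peak_offsets = NULL,
                                hot_mask = NULL) {
  stopifnot(inherits(array, "array_spec"), inherits(irf, "irf_spec"),
            inherits(grid, "sim_grid"))
  if (photons_per_frame < 0) stop("`photons_per_frame` must be >= 0", call. = FALSE)
  if (array$peak_jitter_span_ns > grid_window_ns(grid)) {
    stop("peak jitter span exceeds the measurement window", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))

  nb <- grid$n_bins
  npx <- array$n_rows * array$n_cols

  # temporal profile shared by all pixels (before per-pixel shift)
  irf_curve <- make_irf(irf, grid)
  profile <- if (is.null(tau_ns)) {
    as.numeric(irf_curve)
  } else {
    d <- ground_truth_decay(tau_ns, 1, irf_curve, grid)
    d$counts
  }
  profile <- profile / sum(profile)

  if (!is.null(peak_offsets)) {
    offsets <- as.integer(peak_offsets)
  } else {
    half_span_bins <- floor((array$peak_jitter_span_ns / 2) / grid$bin_width_ns)
    offsets <- if (half_span_bins > 0) {
      sample.int(2L * half_span_bins + 1L, npx, replace = TRUE) -
        half_span_bins - 1L
    } else {
      integer(npx)
    }
  }
  if (!is.null(hot_mask)) {
    hot <- as.logical(hot_mask)
  } else {
    n_hot <- round(array$hot_pixel_fraction * npx)
    hot <- logical(npx)
    if (n_hot > 0) hot[sample.int(npx, n_hot)] <- TRUE
  }

  mean_rate <- photons_per_frame / npx
  counts <- matrix(0, nrow = npx, ncol = nb)

  # normal pixels: grouped by shared offset so the shifted profile is built
  # once per group; counts ~ Poisson(mean_rate * shifted_profile)
  normal_idx <- which(!hot)
  if (length(normal_idx) > 0 && photons_per_frame > 0) {
    off_norm <- offsets[normal_idx]
    for (o in unique(off_norm)) {
      p_shift <- shift_vector(profile, o)
      px <- normal_idx[off_norm == o]
      lam <- mean_rate * p_shift
      counts[px, ] <- matrix(
        stats::rpois(length(px) * nb, rep(lam, each = length(px))),
        nrow = length(px))
    }
  }
  # hot pixels: dark-like, uniform over bins at multiplier x mean pixel rate
  if (any(hot)) {
    lam_hot <- array$hot_pixel_rate_multiplier * mean_rate / nb
    counts[hot, ] <- matrix(stats::rpois(sum(hot) * nb, lam_hot),
                            nrow = sum(hot))
  }
  if (array$dark_rate_per_bin > 0) {
    counts <- counts + matrix(stats::rpois(npx * nb, array$dark_rate_per_bin),
                              nrow = npx)
  }

  structure(list(
    counts = array(counts, dim = c(array$n_rows, array$n_cols, nb)),
    true_peak_offsets = matrix(offsets, array$n_rows, array$n_cols),
    true_hot_mask = matrix(hot, array$n_rows, array$n_cols),
    grid = grid, array = array
  ), class = "spad_frame")
}

#' @export
print.spad_frame <- function(x, ...) {
  cat(sprintf("<spad_frame> %d x %d pixels x %d bins, %.4g total counts, %d hot\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              sum(x$counts), sum(x$true_hot_mask)))
  invisible(x)
}

# Shift a vector by k bins (positive k shifts toward later bins), filling
# with zeros; counts shifted outside the window are dropped.
shift_vector <- function(v, k) {
  n <- length(v)
  out <- numeric(n)
  if (k >= n || k <= -n) return(out)
  if (k >= 0) {
    out[(k + 1L):n] <- v[1L:(n - k)]
  } else {
    out[1L:(n + k)] <- v[(1L - k):n]
  }
  out
}

# Flatten a frame's counts to an n_pixels x n_bins matrix (row-major pixel
# index: pixel = row + n_rows * (col - 1)).
frame_pixel_matrix <- function(frame) {
  d <- dim(frame$counts)
  matrix(frame$counts, nrow = d[1] * d[2], ncol = d[3])
}

# Accumulate a frame or list of frames into one pixel x bin matrix.
accumulate_frames <- function(frames) {
  if (inherits(frames, "spad_frame")) frames <- list(frames)
  if (length(frames) == 0) stop("need at least one frame", call. = FALSE)
  stopifnot(all(vapply(frames, inherits, logical(1), "spad_frame")))
  acc <- frame_pixel_matrix(frames[[1]])
  for (f in frames[-1]) {
    m <- frame_pixel_matrix(f)
    if (!all(dim(m) == dim(acc))) stop("frame geometries differ", call. = FALSE)
    acc <- acc + m
  }
  attr(acc, "grid") <- frames[[1]]$grid
  attr(acc, "geom") <- dim(frames[[1]]$counts)[1:2]
  acc
}
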