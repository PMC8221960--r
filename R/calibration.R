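#' Per-pixel SPAD-array calibration
#'
#' Container for the calibration of a SPAD array used as a single
#' "megapixel" detector: each pixel's IRF peak position (bin index of its
#' timing response) and a mask of hot/defective pixels. During acquisition
#' each pixel's histogram is shifted so its peak lands on `reference_bin`
#' before pixels are summed.
#'
#' @param peak_positions Integer matrix of per-pixel peak bin indices
#'   (`NA` for pixels that could not be calibrated).
#' @param hot_mask Logical matrix, `TRUE` for masked pixels.
#' @param reference_bin Alignment target bin (default 50).
#' @return An object of class `pixel_calibration`.
#' @export
pixel_calibration <- function(peak_positions, hot_mask, reference_bin = 50L) {
  peak_positions <- as.matrix(peak_positions)
  hot_mask <- as.matrix(hot_mask)
  if (!all(dim(peak_positions) == dim(hot_mask))) {
    stop("`peak_positions` and `hot_mask` must have the same shape", call. = FALSE)
  }
  structure(list(peak_positions = peak_positions,
                 hot_mask = hot_mask,
                 reference_bin = as.integer(reference_bin)),
            class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("<pixel_calibration> %d x %d pixels, %d masked, reference bin %d\n",
              nrow(x$peak_positions), ncol(x$peak_positions),
              sum(x$hot_mask), x$reference_bin))
  invisible(x)
}

#' Estimate per-pixel IRF peak positions
#'
#' Frames are accumulated pixel-wise, then each pixel's peak is located by
#' argmax of its accumulated histogram, optionally after a 3-bin
#' moving-average smoothing (on by default; helps low-count pixels where a
#' single stray photon can beat the true peak). Ties break toward the
#' smaller bin index. Pixels with zero total counts get an `NA` peak and are
#' expected to be masked downstream.
#'
#' @param frames A `spad_frame` or list of them.
#' @param smooth Apply 3-bin moving-average smoothing before the argmax?
#' @return Integer matrix of per-pixel peak bin indices (`NA` where a pixel
#'   has no counts).
#' @export
estimate_peak_positions <- function(frames, smooth = TRUE) {
  acc <- accumulate_frames(frames)
  geom <- attr(acc, "geom")
  nb <- ncol(acc)
  if (isTRUE(smooth) && nb >= 3L) {
    sm <- acc[, c(1L, 1L:(nb - 1L))] + acc + acc[, c(2L:nb, nb)]
  } else {
    sm <- acc
  }
  peaks <- max.col(sm, ties.method = "first")
  peaks[rowSums(acc) == 0] <- NA_integer_
  matrix(peaks, geom[1], geom[2])
}

#' Detect hot pixels by total intensity
#'
#' A pixel is flagged hot when its accumulated total count exceeds
#' `k` times the median total count across pixels. With an all-zero array an
#' empty mask is returned with a warning.
#'
#' @param frames A `spad_frame` or list of them.
#' @param k Multiplier on the median total count (default 5).
#' @return Logical matrix of flagged pixels.
#' @export
detect_hot_pixels <- function(frames, k = 5) {
  acc <- accumulate_frames(frames)
  geom <- attr(acc, "geom")
  totals <- rowSums(acc)
  med <- stats::median(totals)
  if (med == 0 && all(totals == 0)) {
    warning("all pixels have zero counts; returning empty hot-pixel mask",
            call. = FALSE)
    return(matrix(FALSE, geom[1], geom[2]))
  }
  flagged <- totals > k * med
  matrix(flagged, geom[1], geom[2])
}

#' Calibrate a SPAD array from IRF-only frames
#'
#' Convenience wrapper running [detect_hot_pixels()] and
#' [estimate_peak_positions()] and bundling them into a
#' [pixel_calibration()]. Pixels with no counts are auto-masked.
#'
#' @inheritParams estimate_peak_positions
#' @inheritParams detect_hot_pixels
#' @param reference_bin Alignment target bin.
#' @return A [pixel_calibration()].
#' @export
calibrate_array <- function(frames, reference_bin = 50L, k = 5, smooth = TRUE) {
  peaks <- estimate_peak_positions(frames, smooth = smooth)
  hot <- detect_hot_pixels(frames, k = k)
  hot[is.na(peaks)] <- TRUE
  pixel_calibration(peaks, hot, reference_bin = reference_bin)
}

#' Align pixel histograms and aggregate into one decay
#'
#' Each unmasked pixel's histogram is shifted by
#' `reference_bin - peak_position` bins (zero fill; counts shifted out of
#' the window are dropped) and the shifted histograms are summed into a
#' single [decay_histogram()] — the array acting as one megapixel.
#'
#' @param frame A `spad_frame`.
#' @param calib A [pixel_calibration()] covering the frame's geometry.
#' @return A [decay_histogram()].
#' @export
align_and_aggregate <- function(frame, calib) {
  stopifnot(inherits(frame, "spad_frame"), inherits(calib, "pixel_calibration"))
  d <- dim(frame$counts)
  if (!all(d[1:2] == dim(calib$peak_positions))) {
    stop("calibration geometry does not match the frame", call. = FALSE)
  }
  m <- frame_pixel_matrix(frame)
  nb <- d[3]
  peaks <- as.vector(calib$peak_positions)
  masked <- as.vector(calib$hot_mask) | is.na(peaks)
  shifts <- calib$reference_bin - peaks
  agg <- numeric(nb)
  use <- which(!masked)
  for (s in unique(shifts[use])) {
    px <- use[shifts[use] == s]
    rowsum_s <- colSums(m[px, , drop = FALSE])
    agg <- agg + shift_vector(rowsum_s, s)
  }
  decay_histogram(agg, frame$grid)
}

#' Sum pixels without alignment
#'
#' The uncalibrated megapixel histogram: all pixel histograms summed as-is
#' (optionally excluding masked pixels). Useful for before/after comparisons
#' of the integrated IRF.
#'
#' @param frame A `spad_frame`.
#' @param hot_mask Optional logical matrix of pixels to exclude.
#' @return A [decay_histogram()].
#' @export
aggregate_unaligned <- function(frame, hot_mask = NULL) {
  stopifnot(inherits(frame, "spad_frame"))
  m <- frame_pixel_matrix(frame)
  if (!is.null(hot_mask)) m <- m[!as.vector(hot_mask), , drop = FALSE]
  decay_histogram(colSums(m), frame$grid)
}

#' Subtract the leading-bins background estimate
#'
#' Estimates the background level as the mean count over the first
#' `n_lead_bins` bins (which should precede the IRF rise) and subtracts it
#' from every bin, clamping at 0. A warning is issued when the histogram's
#' peak falls inside the leading window, since the "background" would then
#' include signal.
#'
#' @param hist A [decay_histogram()].
#' @param n_lead_bins Number of leading bins used for the background
#'   estimate (default 50).
#' @return A background-subtracted [decay_histogram()]; the estimated level
#'   is stored in attribute `background_level`.
#' @export
subtract_background <- function(hist, n_lead_bins = 50L) {
  stopifnot(inherits(hist, "decay_histogram"))
  n_lead_bins <- as.integer(n_lead_bins)
  if (n_lead_bins < 1L || n_lead_bins >= hist$grid$n_bins) {
    stop("`n_lead_bins` must be in [1, n_bins)", call. = FALSE)
  }
  if (which.max(hist$counts) <= n_lead_bins) {
    warning("histogram peak lies within the leading background window",
            call. = FALSE)
  }
  bg <- mean(hist$counts[seq_len(n_lead_bins)])
  out <- decay_histogram(pmax(hist$counts - bg, 0), hist$grid)
  attr(out, "background_level") <- bg
  out
}

#' Full width at half maximum of a histogram
#'
#' Locates the peak and linearly interpolates the half-maximum crossings on
#' each side, returning their distance in ns. Errors when either side never
#' falls below half maximum inside the window.
#'
#' @param hist A [decay_histogram()].
#' @return FWHM in ns.
#' @examples
#' g <- sim_grid()
#' measure_fwhm(decay_histogram(make_irf(irf_spec(), g) * 1000, g))
#' @export
measure_fwhm <- function(hist) {
  stopifnot(inherits(hist, "decay_histogram"))
  y <- hist$counts
  t <- bin_times_ns(hist$grid)
  ipk <- which.max(y)
  half <- y[ipk] / 2
  # left crossing
  left_below <- which(y[seq_len(ipk)] < half)
  if (length(left_below) == 0) {
    stop("half maximum not reached on the left side of the peak", call. = FALSE)
  }
  il <- max(left_below)
  tl <- t[il] + (half - y[il]) / (y[il + 1L] - y[il]) * (t[il + 1L] - t[il])
  # right crossing
  right_below <- which(y[ipk:length(y)] < half)
  if (length(right_below) == 0) {
    stop("half maximum not reached on the right side of the peak", call. = FALSE)
  }
  ir <- ipk + min(right_below) - 1L
  tr <- t[ir - 1L] + (half - y[ir - 1L]) / (y[ir] - y[ir - 1L]) * (t[ir] - t[ir - 1L])
  tr - tl
}
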