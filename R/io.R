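#' Read and write decay histograms as CSV
#'
#' The histogram CSV dialect has a header `bin_index,time_ns,counts` with
#' 1-based `bin_index` and `time_ns = (bin_index - 0.5) * h`; the bin width
#' is recovered from the time column. Round trips are lossless for counts
#' and grid metadata.
#'
#' @param path File path.
#' @return `read_histogram()` returns a [decay_histogram()];
#'   `write_histogram()` invisibly returns `path`.
#' @export
read_histogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bin_index", "time_ns", "counts")
  if (!all(req %in% names(df))) {
    stop(sprintf("malformed histogram CSV: expected header %s",
                 paste(req, collapse = ",")), call. = FALSE)
  }
  if (any(!is.finite(df$counts))) {
    stop(sprintf("non-finite count at row %d", which(!is.finite(df$counts))[1]),
         call. = FALSE)
  }
  if (any(df$counts < 0)) {
    stop(sprintf("negative count at row %d", which(df$counts < 0)[1]),
         call. = FALSE)
  }
  if (!identical(as.integer(df$bin_index), seq_len(nrow(df)))) {
    stop("bin_index must run 1..n_bins in order", call. = FALSE)
  }
  h <- 2 * df$time_ns[1]  # time of bin 1 is h/2
  decay_histogram(df$counts, sim_grid(nrow(df), h))
}

#' @rdname read_histogram
#' @param hist A [decay_histogram()].
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  df <- as_tibble(hist)
  # full-precision counts so the round trip is bit-exact
  df$counts <- sprintf("%.17g", df$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write SPAD frame stacks as CSV + JSON sidecar
#'
#' A frame stack is stored as a long-format CSV (`frame,row,col,bin,counts`,
#' zero rows omitted) plus a JSON sidecar `<path>.meta.json` carrying the
#' grid (`n_bins`, `bin_width_ns`), the geometry and — for simulator output
#' — the ground-truth peak offsets and hot mask. Plain-text throughout.
#'
#' @param frames A `spad_frame` or list of them.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_frames()` invisibly returns `path`; `read_frames()`
#'   returns a list of `spad_frame` objects.
#' @export
write_frames <- function(frames, path) {
  if (inherits(frames, "spad_frame")) frames <- list(frames)
  stopifnot(all(vapply(frames, inherits, logical(1), "spad_frame")))
  rows <- lapply(seq_along(frames), function(fi) {
    f <- frames[[fi]]
    nz <- which(f$counts != 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) return(NULL)
    data.frame(frame = fi, row = nz[, 1], col = nz[, 2], bin = nz[, 3],
               counts = f$counts[nz])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  f1 <- frames[[1]]
  meta <- list(
    n_frames = length(frames),
    n_rows = dim(f1$counts)[1], n_cols = dim(f1$counts)[2],
    grid = list(n_bins = f1$grid$n_bins, bin_width_ns = f1$grid$bin_width_ns),
    truth = list(peak_offsets = as.vector(f1$true_peak_offsets),
                 hot_mask = as.vector(f1$true_hot_mask))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("frame stack sidecar missing: %s", meta_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("n_frames", "n_rows", "n_cols", "grid")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("frame stack sidecar missing attribute `%s`", field),
           call. = FALSE)
    }
  }
  if (is.null(meta$grid$n_bins) || is.null(meta$grid$bin_width_ns)) {
    stop("frame stack sidecar missing grid attributes `n_bins`/`bin_width_ns`",
         call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (any(df$counts < 0)) {
    stop(sprintf("negative count at row %d", which(df$counts < 0)[1]),
         call. = FALSE)
  }
  grid <- sim_grid(meta$grid$n_bins, meta$grid$bin_width_ns)
  arr_sp <- array_spec(meta$n_rows, meta$n_cols, peak_jitter_span_ns = 0,
                       hot_pixel_fraction = 0, dark_rate_per_bin = 0)
  lapply(seq_len(meta$n_frames), function(fi) {
    a <- array(0, dim = c(meta$n_rows, meta$n_cols, grid$n_bins))
    sub <- df[df$frame == fi, , drop = FALSE]
    a[cbind(sub$row, sub$col, sub$bin)] <- sub$counts
    structure(list(
      counts = a,
      true_peak_offsets = matrix(meta$truth$peak_offsets %||% 0L,
                                 meta$n_rows, meta$n_cols),
      true_hot_mask = matrix(meta$truth$hot_mask %||% FALSE,
                             meta$n_rows, meta$n_cols),
      grid = grid, array = arr_sp
    ), class = "spad_frame")
  })
}

#' Read and write pixel calibrations
#'
#' Calibrations are stored as a CSV of per-pixel records
#' (`row,col,peak_bin,hot`) plus a JSON sidecar with the geometry and
#' `reference_bin`.
#'
#' @param calib A [pixel_calibration()].
#' @param path CSV path.
#' @return `write_calibration()` invisibly returns `path`;
#'   `read_calibration()` returns a [pixel_calibration()].
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "pixel_calibration"))
  d <- dim(calib$peak_positions)
  df <- data.frame(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    peak_bin = as.vector(calib$peak_positions),
    hot = as.vector(calib$hot_mask)
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(n_rows = d[1], n_cols = d[2], reference_bin = calib$reference_bin),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  pixel_calibration(
    matrix(df$peak_bin, meta$n_rows, meta$n_cols),
    matrix(df$hot, meta$n_rows, meta$n_cols),
    reference_bin = meta$reference_bin
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
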