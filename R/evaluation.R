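#' Accuracy of a lifetime estimator, in dB
#'
#' `Acc.(dB) = 20 log10(tau / |dtau|)` where `dtau` is the absolute error of
#' the mean estimate, `|mean(tau_est) - tau_true|`. Higher is better; equal
#' error and lifetime give 0 dB. A zero error yields an infinite value,
#' reported as the `cap_db` sentinel (default 100 dB) so downstream
#' aggregation stays total.
#'
#' @param tau_true True lifetime (> 0), ns.
#' @param tau_est Vector of lifetime estimates, ns.
#' @param cap_db Sentinel/cap for infinite or huge values (default 100).
#' @return Accuracy in dB.
#' @examples
#' accuracy_db(2, rep(2.2, 10)) # 20 dB
#' @export
accuracy_db <- function(tau_true, tau_est, cap_db = 100) {
  if (length(tau_est) == 0L) stop("empty estimate set", call. = FALSE)
  if (!is.finite(tau_true) || tau_true <= 0) {
    stop("`tau_true` must be positive", call. = FALSE)
  }
  dtau <- abs(mean(tau_est) - tau_true)
  if (dtau == 0) return(cap_db)
  min(20 * log10(tau_true / dtau), cap_db)
}

#' Precision of a lifetime estimator, in dB
#'
#' `Prec.(dB) = 20 log10(tau / sigma_tau)` with `sigma_tau` the sample
#' standard deviation of the estimates. Zero spread yields the `cap_db`
#' sentinel.
#'
#' @inheritParams accuracy_db
#' @return Precision in dB.
#' @export
precision_db <- function(tau_true, tau_est, cap_db = 100) {
  if (length(tau_est) < 2L) stop("need >= 2 estimates for a spread", call. = FALSE)
  if (!is.finite(tau_true) || tau_true <= 0) {
    stop("`tau_true` must be positive", call. = FALSE)
  }
  s <- stats::sd(tau_est)
  if (s == 0) return(cap_db)
  min(20 * log10(tau_true / s), cap_db)
}

#' Accuracy/precision sweep versus photon count
#'
#' Benchmarks estimators over a grid of photon-count bins. Within each
#' `N_T` bin, decays are simulated for every lifetime on `tau_grid` with
#' `replicates` noisy realizations each (noise level per the dataset spec's
#' sigma rule); identical samples are fed to every estimator. Accuracy and
#' precision (dB) are computed per lifetime from the replicate set and then
#' averaged over the lifetime grid, giving the bin's mean accuracy and mean
#' precision per estimator.
#'
#' @param estimators Named list of estimator functions; each receives a
#'   counts matrix (samples x bins) and the [sim_grid()] and must return a
#'   numeric vector of lifetime estimates in ns (`NA` allowed for failures,
#'   dropped with their sample from both metrics).
#' @param test_spec A [dataset_spec()]; supplies the noise rule and seed.
#' @param nt_bins Two-column matrix or data frame of bin edges
#'   (`nt_low`, `nt_high`), or `NULL` for 20 equal-width bins over the
#'   spec's `nt_range`.
#' @param irf IRF curve used to simulate the test decays.
#' @param grid A [sim_grid()].
#' @param tau_grid Lifetimes simulated in every bin (default 8 values evenly
#'   spanning the spec's tau range, trimmed 10% from each end).
#' @param replicates Noisy realizations per (lifetime, bin) cell
#'   (default 30).
#' @return A tibble of class `flim_sweep`: `estimator`, `nt_low`, `nt_high`,
#'   `n_samples`, `mean_accuracy_db`, `mean_precision_db`.
#' @export
sweep_vs_counts <- function(estimators, test_spec = dataset_spec(),
                            nt_bins = NULL, irf = NULL, grid = sim_grid(),
                            tau_grid = NULL, replicates = 30L) {
  stopifnot(is.list(estimators), length(estimators) > 0,
            !is.null(names(estimators)), inherits(test_spec, "dataset_spec"))
  if (is.null(irf)) irf <- make_irf(irf_spec(), grid)
  if (is.null(nt_bins)) {
    edges <- seq(test_spec$nt_range[1], test_spec$nt_range[2], length.out = 21L)
    nt_bins <- cbind(edges[-length(edges)], edges[-1])
  }
  nt_bins <- as.matrix(nt_bins)
  if (any(nt_bins[, 1] >= nt_bins[, 2])) {
    stop("each nt bin needs nt_low < nt_high", call. = FALSE)
  }
  if (is.null(tau_grid)) {
    r <- test_spec$tau_range_ns
    span <- diff(r)
    tau_grid <- seq(r[1] + 0.1 * span, r[2] - 0.1 * span, length.out = 8L)
  }
  set.seed(test_spec$seed)
  out <- list()
  for (b in seq_len(nrow(nt_bins))) {
    lo <- nt_bins[b, 1]; hi <- nt_bins[b, 2]
    n_cell <- length(tau_grid) * replicates
    tau_s <- rep(tau_grid, each = replicates)
    nt_s <- stats::runif(n_cell, lo, hi)
    sig_s <- stats::runif(n_cell, pmin(1, nt_s / test_spec$sigma_max_divisor),
                          nt_s / test_spec$sigma_max_divisor)
    counts <- matrix(0, n_cell, grid$n_bins)
    for (i in seq_len(n_cell)) {
      y <- decay_conv(as.numeric(irf), tau_s[i], grid)
      y <- y / sum(y) * nt_s[i]
      counts[i, ] <- pmax(y + sqrt(y) * stats::rnorm(grid$n_bins) +
                            stats::rnorm(grid$n_bins, sd = sig_s[i]), 0)
    }
    for (nm in names(estimators)) {
      est <- estimators[[nm]](counts, grid)
      accs <- precs <- numeric(0)
      for (tv in tau_grid) {
        sel <- tau_s == tv & is.finite(est)
        if (sum(sel) >= 2L) {
          accs <- c(accs, accuracy_db(tv, est[sel]))
          precs <- c(precs, precision_db(tv, est[sel]))
        }
      }
      if (length(accs) == 0L) {
        warning(sprintf("bin [%g, %g] empty for estimator %s; omitted", lo, hi, nm),
                call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        estimator = nm, nt_low = lo, nt_high = hi,
        n_samples = n_cell, mean_accuracy_db = mean(accs),
        mean_precision_db = mean(precs))
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("flim_sweep", class(res))
  res
}

#' Per-frame event detection and lifetime analysis
#'
#' Emulates flowing-particle analysis: each frame's aggregated, calibrated
#' histogram is one decay. Frames whose total count exceeds the intensity
#' threshold become detected events; each event's lifetime is estimated
#' from that single frame. The background level is the mean intensity of
#' the sub-threshold frames.
#'
#' @param frame_histograms List of [decay_histogram()] objects, one per
#'   frame (or a samples x bins matrix plus `grid`).
#' @param estimator Function taking a counts matrix and a [sim_grid()],
#'   returning lifetimes in ns (as in [sweep_vs_counts()]).
#' @param threshold_pc Intensity threshold in photon counts (default 400).
#' @param grid Required when `frame_histograms` is a matrix.
#' @param method Method tag recorded on the events (default `"est"`).
#' @return List of class `frame_events`: `events` tibble (`frame_index`,
#'   `intensity_pc`, `tau_ns`, `method`), `background_pc` (mean
#'   sub-threshold intensity, `NaN` when every frame is an event) and
#'   `threshold_pc`.
#' @export
frame_event_analysis <- function(frame_histograms, estimator,
                                 threshold_pc = 400, grid = NULL,
                                 method = "est") {
  if (is.matrix(frame_histograms)) {
    stopifnot(inherits(grid, "sim_grid"))
    counts <- frame_histograms
  } else {
    if (length(frame_histograms) == 0L) stop("no frames supplied", call. = FALSE)
    stopifnot(all(vapply(frame_histograms, inherits, logical(1), "decay_histogram")))
    grid <- frame_histograms[[1]]$grid
    counts <- do.call(rbind, lapply(frame_histograms, function(h) h$counts))
  }
  if (nrow(counts) == 0L) stop("no frames supplied", call. = FALSE)
  intensity <- rowSums(counts)
  is_event <- intensity > threshold_pc
  background <- mean(intensity[!is_event])
  events <- tibble::tibble(frame_index = integer(), intensity_pc = numeric(),
                           tau_ns = numeric(), method = character())
  if (any(is_event)) {
    tau <- estimator(counts[is_event, , drop = FALSE], grid)
    events <- tibble::tibble(frame_index = which(is_event),
                             intensity_pc = intensity[is_event],
                             tau_ns = tau, method = method)
  }
  structure(list(events = events, background_pc = background,
                 threshold_pc = threshold_pc),
            class = "frame_events")
}

#' @export
print.frame_events <- function(x, ...) {
  cat(sprintf("<frame_events> %d events above %g p.c., background %.4g p.c.\n",
              nrow(x$events), x$threshold_pc, x$background_pc))
  invisible(x)
}

#' Bin event lifetimes and intensities for display
#'
#' Histograms the detected events with the conventional display binning:
#' 0.5 ns lifetime bins and 20 p.c. intensity bins.
#'
#' @param events A [frame_event_analysis()] result or its `events` tibble.
#' @param tau_bin_ns Lifetime bin width (default 0.5).
#' @param intensity_bin_pc Intensity bin width (default 20).
#' @return List of two tibbles, `lifetime` (`tau_mid_ns`, `n`) and
#'   `intensity` (`intensity_mid_pc`, `n`).
#' @export
bin_events <- function(events, tau_bin_ns = 0.5, intensity_bin_pc = 20) {
  ev <- if (inherits(events, "frame_events")) events$events else events
  bin_tbl <- function(x, w, nm) {
    idx <- floor(x / w)
    tb <- table(idx)
    tibble::tibble("{nm}" := (as.numeric(names(tb)) + 0.5) * w,
                   n = as.integer(tb))
  }
  list(lifetime = bin_tbl(ev$tau_ns, tau_bin_ns, "tau_mid_ns"),
       intensity = bin_tbl(ev$intensity_pc, intensity_bin_pc, "intensity_mid_pc"))
}

#' Summarize event lifetimes against a reference
#'
#' Mean, standard deviation and relative bias
#' `(tau_mean - tau_ref) / tau_ref` of the event lifetimes.
#'
#' @param events A [frame_event_analysis()] result or an `events` tibble
#'   with a `tau_ns` column (or a bare numeric vector).
#' @param tau_ref Reference lifetime in ns.
#' @return One-row tibble: `tau_mean_ns`, `tau_sd_ns`, `bias` (fraction),
#'   `bias_pct`, `n_events`.
#' @examples
#' summarize_bias(c(2.3, 2.3), 2.1)$bias_pct # 9.52
#' @export
summarize_bias <- function(events, tau_ref) {
  tau <- if (inherits(events, "frame_events")) {
    events$events$tau_ns
  } else if (is.data.frame(events)) {
    events$tau_ns
  } else {
    as.numeric(events)
  }
  if (length(tau) == 0L) stop("no events to summarize", call. = FALSE)
  m <- mean(tau)
  tibble::tibble(tau_mean_ns = m,
                 tau_sd_ns = if (length(tau) > 1L) stats::sd(tau) else NA_real_,
                 bias = (m - tau_ref) / tau_ref,
                 bias_pct = 100 * (m - tau_ref) / tau_ref,
                 n_events = length(tau))
}

#' Standard estimator wrappers for sweeps
#'
#' Convenience constructors turning package estimators into the
#' `function(counts, grid)` shape consumed by [sweep_vs_counts()] and
#' [frame_event_analysis()].
#'
#' @param config A [cmm_config()].
#' @param irf_hist Optional IRF [decay_histogram()] for CMM calibration.
#' @param fit A trained `qcnn` or `qcnn_fit`.
#' @return A `function(counts, grid)` returning lifetimes in ns.
#' @export
cmm_estimator <- function(config = cmm_config(), irf_hist = NULL) {
  force(config); force(irf_hist)
  function(counts, grid) {
    cmm_lifetime_matrix(counts, grid, config, irf_hist)$tau_ns
  }
}

#' @rdname cmm_estimator
#' @export
qcnn_estimator <- function(fit) {
  net <- if (inherits(fit, "qcnn_fit")) fit$net else fit
  stopifnot(inherits(net, "qcnn"))
  function(counts, grid) {
    predict.qcnn(net, counts)$tau_ns
  }
}
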