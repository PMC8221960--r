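#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decay histogram
#'
#' @param object A [decay_histogram()].
#' @param log_y Log-scale the count axis? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_histogram <- function(object, log_y = TRUE, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns, y = .data$counts)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ns)", y = "photon counts") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot QCNN training curves
#'
#' @param object A [train_qcnn()] result.
#' @param ... Unused.
#' @return A ggplot of train/validation MSE versus epoch.
#' @export
autoplot.qcnn_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$mse,
                               color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = expression(MSE ~ (ns^2)), color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an accuracy/precision sweep
#'
#' @param object A [sweep_vs_counts()] result.
#' @param ... Unused.
#' @return A faceted ggplot of mean accuracy and precision (dB) versus the
#'   photon-count bin center, one line per estimator.
#' @export
autoplot.flim_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("mean_accuracy_db", "mean_precision_db"),
                            names_to = "metric", values_to = "db")
  df$metric <- ifelse(df$metric == "mean_accuracy_db", "accuracy", "precision")
  df$nt_mid <- (df$nt_low + df$nt_high) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nt_mid, y = .data$db,
                                   color = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(N[T] ~ "(photon counts)"), y = "dB",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Intensity-lifetime scatter of detected events
#'
#' @param object A [frame_event_analysis()] result.
#' @param ... Unused.
#' @return A ggplot scatter of event intensity versus estimated lifetime.
#' @export
autoplot.frame_events <- function(object, ...) {
  ggplot2::ggplot(object$events,
                  ggplot2::aes(x = .data$tau_ns, y = .data$intensity_pc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "lifetime (ns)", y = "intensity (p.c.)") +
    ggplot2::theme_minimal()
}
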