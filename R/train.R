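#' QCNN training configuration
#'
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 128).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param seed Integer seed for shuffling and initialization (independent of
#'   the dataset seed).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L,
                         learning_rate = 1e-4, seed = 1L) {
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0) {
    stop("epochs, batch_size and learning_rate must all be positive", call. = FALSE)
  }
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

# row-wise input normalization per the model's fixed rule
normalize_input <- function(X, rule) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  denom <- switch(rule,
                  max = apply(X, 1L, max),
                  total = rowSums(X))
  denom[denom <= 0] <- 1
  X / denom
}

adam_init <- function(p) list(m = p * 0, v = p * 0)

adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train a QCNN lifetime regressor
#'
#' Quantization-aware training: the forward pass uses quantized weights and
#' activations (per the model's [quant_scheme()]); the backward pass treats
#' every quantizer as the identity (straight-through estimator). The loss is
#' mean squared error on the lifetime in ns, optimized with Adam.
#' Deterministic given the config seed. Training aborts with diagnostics if
#' the loss diverges to `NaN`.
#'
#' @param net A model from [build_network()].
#' @param dataset A [sample_dataset()] result (train/validation split used
#'   as labeled).
#' @param config A [train_config()].
#' @param verbose Print one line per 10 epochs? Default `FALSE`.
#' @return An object of class `qcnn_fit`: the trained model (`$net`), the
#'   per-epoch loss curves (`$history`, a tibble with `epoch`, `train_mse`,
#'   `val_mse`), and the configs. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
train_qcnn <- function(net, dataset, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "qcnn"), inherits(dataset, "decay_dataset"),
            inherits(config, "train_config"))
  set.seed(config$seed)
  X_all <- normalize_input(dataset$counts, net$normalization)
  y_all <- dataset$meta$tau_ns
  tr <- which(dataset$meta$split == "train")
  va <- which(dataset$meta$split == "validation")
  if (length(tr) == 0L) stop("dataset has no training samples", call. = FALSE)
  Xtr <- X_all[tr, , drop = FALSE]; ytr <- y_all[tr]
  Xva <- X_all[va, , drop = FALSE]; yva <- y_all[va]

  n_tr <- nrow(Xtr)
  bs <- min(config$batch_size, n_tr)
  state <- list(blocks = lapply(net$blocks, function(bl) {
    list(W = adam_init(bl$W), g = adam_init(bl$bn_gamma), b = adam_init(bl$bn_beta))
  }), head_W = adam_init(net$head$W), head_b = adam_init(net$head$b))
  t_step <- 0L
  hist_tr <- hist_va <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0; n_seen <- 0
    for (start in seq(1L, n_tr, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n_tr)]
      bp <- qcnn_backprop(net, Xtr[idx, , drop = FALSE], ytr[idx])
      if (!is.finite(bp$loss)) {
        stop(sprintf("training diverged (loss %s) at epoch %d", bp$loss, ep),
             call. = FALSE)
      }
      net <- bp$net
      t_step <- t_step + 1L
      lr <- config$learning_rate
      for (i in 1:4) {
        up <- adam_step(net$blocks[[i]]$W, bp$grads[[i]]$dW,
                        state$blocks[[i]]$W, lr, t_step)
        net$blocks[[i]]$W <- up$p; state$blocks[[i]]$W <- up$st
        up <- adam_step(net$blocks[[i]]$bn_gamma, bp$grads[[i]]$dgamma,
                        state$blocks[[i]]$g, lr, t_step)
        net$blocks[[i]]$bn_gamma <- up$p; state$blocks[[i]]$g <- up$st
        up <- adam_step(net$blocks[[i]]$bn_beta, bp$grads[[i]]$dbeta,
                        state$blocks[[i]]$b, lr, t_step)
        net$blocks[[i]]$bn_beta <- up$p; state$blocks[[i]]$b <- up$st
      }
      up <- adam_step(net$head$W, bp$dWh, state$head_W, lr, t_step)
      net$head$W <- up$p; state$head_W <- up$st
      up <- adam_step(net$head$b, bp$dbh, state$head_b, lr, t_step)
      net$head$b <- up$p; state$head_b <- up$st
      ep_loss <- ep_loss + bp$loss * length(idx)
      n_seen <- n_seen + length(idx)
    }
    hist_tr[ep] <- ep_loss / n_seen
    hist_va[ep] <- if (length(va) > 0) {
      qcnn_mse(net, Xva, yva)
    } else NA_real_
    if (verbose && ep %% 10L == 0L) {
      message(sprintf("epoch %3d  train MSE %.4f  val MSE %.4f",
                      ep, hist_tr[ep], hist_va[ep]))
    }
  }

  net$trained <- TRUE
  structure(list(
    net = net,
    history = tibble::tibble(epoch = seq_len(config$epochs),
                             train_mse = hist_tr, val_mse = hist_va),
    config = config,
    dataset_spec = dataset$spec
  ), class = "qcnn_fit")
}

# evaluation-mode MSE in manageable chunks
qcnn_mse <- function(net, X, y, chunk = 4096L) {
  n <- nrow(X)
  se <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    p <- qcnn_forward(net, X[idx, , drop = FALSE], train = FALSE)$pred
    se <- se + sum((p - y[idx])^2)
  }
  se / n
}

#' @export
print.qcnn_fit <- function(x, ...) {
  cat(sprintf("<qcnn_fit> %d epochs, final val MSE %.4g ns^2 (best %.4g)\n",
              nrow(x$history), x$history$val_mse[nrow(x$history)],
              min(x$history$val_mse, na.rm = TRUE)))
  invisible(x)
}

#' Tidy the training history of a QCNN fit
#'
#' @param x A [train_qcnn()] result.
#' @param ... Unused.
#' @return Long tibble: `epoch`, `set` (`train`/`validation`), `mse`.
#' @export
tidy.qcnn_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "set", values_to = "mse") |>
    dplyr::mutate(set = ifelse(.data$set == "train_mse", "train", "validation"))
}

#' Glance at a QCNN fit
#'
#' @param x A [train_qcnn()] result.
#' @param ... Unused.
#' @return One-row tibble: best/final/plateau validation MSE, epochs,
#'   parameter count and bit widths. The plateau value is the median
#'   validation MSE over the last quarter of epochs.
#' @export
glance.qcnn_fit <- function(x, ...) {
  nv <- x$history$val_mse
  last_q <- nv[seq(max(1L, floor(length(nv) * 0.75)), length(nv))]
  tibble::tibble(
    epochs = nrow(x$history),
    best_val_mse = min(nv, na.rm = TRUE),
    final_val_mse = nv[length(nv)],
    plateau_val_mse = stats::median(last_q, na.rm = TRUE),
    n_parameters = n_parameters(x$net),
    w_bits = as.character(x$net$quant$w_bits),
    a_bits = as.character(x$net$quant$a_bits)
  )
}

#' Predict lifetimes with a trained QCNN
#'
#' Normalizes each histogram per the model's fixed rule, runs the forward
#' pass in evaluation mode (deterministic) and clips predictions at the
#' physical floor. Inputs whose background-subtracted total count falls
#' below `min_signal` are flagged `low_signal` — they lie outside the
#' training manifold and the estimate is unreliable.
#'
#' @param object A trained `qcnn` or `qcnn_fit`.
#' @param hist A [decay_histogram()], a matrix (samples x bins), or a
#'   [sample_dataset()] result.
#' @param floor_ns Lower clip for predictions (default 0).
#' @param min_signal Low-signal flag threshold on background-subtracted
#'   total counts (default 50, half the minimum trained photon total).
#' @param ... Unused.
#' @return Tibble: `sample_id`, `tau_ns`, `method = "QCNN"`, `flag`
#'   (`"ok"` or `"low_signal"`).
#' @export
predict.qcnn <- function(object, hist, floor_ns = 0, min_signal = 50, ...) {
  net <- object
  if (inherits(hist, "decay_histogram")) {
    X <- matrix(hist$counts, nrow = 1L)
  } else if (inherits(hist, "decay_dataset")) {
    X <- hist$counts
  } else if (is.matrix(hist)) {
    X <- hist
  } else {
    stop("`hist` must be a decay_histogram, matrix or decay_dataset", call. = FALSE)
  }
  if (ncol(X) != net$n_bins) {
    stop(sprintf("histogram length %d does not match the trained input size %d",
                 ncol(X), net$n_bins), call. = FALSE)
  }
  # background-subtracted signal estimate for the out-of-domain flag
  n_lead <- min(50L, net$n_bins - 1L)
  bg <- rowMeans(X[, seq_len(n_lead), drop = FALSE])
  signal <- rowSums(pmax(X - bg, 0))
  Xn <- normalize_input(X, net$normalization)
  preds <- numeric(nrow(Xn))
  for (start in seq(1L, nrow(Xn), by = 4096L)) {
    idx <- start:min(start + 4095L, nrow(Xn))
    preds[idx] <- qcnn_forward(net, Xn[idx, , drop = FALSE], train = FALSE)$pred
  }
  tibble::tibble(sample_id = seq_len(nrow(Xn)),
                 tau_ns = pmax(preds, floor_ns),
                 method = "QCNN",
                 flag = ifelse(signal < min_signal, "low_signal", "ok"))
}

#' @rdname predict.qcnn
#' @export
predict.qcnn_fit <- function(object, hist, floor_ns = 0, min_signal = 50, ...) {
  predict.qcnn(object$net, hist, floor_ns = floor_ns, min_signal = min_signal, ...)
}

#' Quantization ablation grid
#'
#' Trains one model per (weight bits, activation bits) cell on identical
#' data with identical seeds and reports the best (minimum) validation MSE
#' per cell, quantifying how far each bit-width configuration degrades the
#' regression.
#'
#' @param dataset A [sample_dataset()] result, shared across cells.
#' @param cells Data frame with columns `w_bits`, `a_bits` (entries integer
#'   or `"full"`).
#' @param spec A [network_spec()].
#' @param config A [train_config()]; the same seed is reused in every cell.
#' @param verbose Passed to [train_qcnn()].
#' @return Tibble: `w_bits`, `a_bits`, `best_val_mse`, `plateau_val_mse`.
#' @export
ablate_quantization <- function(dataset, cells, spec = network_spec(),
                                config = train_config(), verbose = FALSE) {
  stopifnot(is.data.frame(cells), all(c("w_bits", "a_bits") %in% names(cells)))
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    q <- quant_scheme(cells$w_bits[[i]], cells$a_bits[[i]])
    net <- build_network(spec, q, n_bins = ncol(dataset$counts),
                         seed = config$seed)
    fit <- train_qcnn(net, dataset, config, verbose = verbose)
    g <- glance(fit)
    res[[i]] <- tibble::tibble(
      w_bits = as.character(cells$w_bits[[i]]),
      a_bits = as.character(cells$a_bits[[i]]),
      best_val_mse = g$best_val_mse,
      plateau_val_mse = g$plateau_val_mse
    )
  }
  dplyr::bind_rows(res)
}
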