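#' Quantization scheme for the QCNN
#'
#' Bit widths of the quantized convolution blocks' weights and activations.
#' `"full"` disables quantization of that component.
#'
#' @param w_bits Weight bit width (integer >= 1) or `"full"` (default 1).
#' @param a_bits Activation bit width (integer >= 1) or `"full"` (default 4).
#' @return An object of class `quant_scheme`.
#' @export
quant_scheme <- function(w_bits = 1L, a_bits = 4L) {
  chk <- function(b, nm) {
    if (identical(b, "full")) return("full")
    b <- as.integer(b)
    if (is.na(b) || b < 1L) {
      stop(sprintf("`%s` must be an integer >= 1 or \"full\"", nm), call. = FALSE)
    }
    b
  }
  structure(list(w_bits = chk(w_bits, "w_bits"), a_bits = chk(a_bits, "a_bits")),
            class = "quant_scheme")
}

#' @export
print.quant_scheme <- function(x, ...) {
  cat(sprintf("<quant_scheme> W_b = %s, A_b = %s\n", x$w_bits, x$a_bits))
  invisible(x)
}

#' QCNN architecture specification
#'
#' Five 1-D convolution blocks. The first two have large kernels and strides
#' to condense the 300-bin histogram; the last three are pointwise
#' (kernel 1). Blocks 1-4 are convolution + batch normalization + ReLU; the
#' fifth block is the linear output head, applied after global average
#' pooling over the remaining positions, producing one scalar (the lifetime
#' in ns). Quantization, when enabled, applies to the three middle blocks
#' (2-4): their weights and their input activations. The first and last
#' blocks always stay full precision.
#'
#' @param blocks List of five lists with fields `filters`, `kernel`,
#'   `stride`, `quantized`. The default reproduces the package's standard
#'   architecture (16x25s4, 32x20s4, 64x1, 32x1, head 1x1).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(blocks = NULL) {
  if (is.null(blocks)) {
    blocks <- list(
      list(filters = 16L, kernel = 25L, stride = 4L, quantized = FALSE),
      list(filters = 32L, kernel = 20L, stride = 4L, quantized = TRUE),
      list(filters = 64L, kernel = 1L, stride = 1L, quantized = TRUE),
      list(filters = 32L, kernel = 1L, stride = 1L, quantized = TRUE),
      list(filters = 1L, kernel = 1L, stride = 1L, quantized = FALSE)
    )
  }
  if (length(blocks) != 5L) stop("exactly 5 blocks required", call. = FALSE)
  for (i in 3:5) {
    if (blocks[[i]]$kernel != 1L) {
      stop("blocks 3-5 must be pointwise (kernel 1)", call. = FALSE)
    }
  }
  if (isTRUE(blocks[[1]]$quantized) || isTRUE(blocks[[5]]$quantized)) {
    stop("first and last blocks must stay full precision", call. = FALSE)
  }
  if (blocks[[5]]$filters != 1L) stop("output head must have 1 filter", call. = FALSE)
  structure(list(blocks = blocks), class = "network_spec")
}

#' Count trainable parameters of a QCNN
#'
#' @param net A model from [build_network()].
#' @return Total number of weights, biases and batch-norm parameters.
#' @export
n_parameters <- function(net) {
  stopifnot(inherits(net, "qcnn"))
  n <- 0
  for (bl in net$blocks) {
    n <- n + length(bl$W) + 2L * length(bl$bn_gamma)
  }
  n + length(net$head$W) + length(net$head$b)
}

#' Build a quantized 1-D CNN lifetime regressor
#'
#' Instantiates the network described by a [network_spec()] with a
#' [quant_scheme()]: convolution weights (He-initialized), batch-norm
#' parameters and the linear head. The model maps a normalized length-`n_bins`
#' histogram to a single lifetime in ns. Convolutions in blocks 1-4 carry no
#' bias (the following batch normalization absorbs it); the head has a bias.
#'
#' @param spec A [network_spec()].
#' @param quant A [quant_scheme()].
#' @param n_bins Input histogram length (default 300).
#' @param normalization Input normalization rule: `"max"` (divide by the
#'   maximum bin, default) or `"total"` (divide by the photon total).
#' @param head Output head: `"gap"` (default; global average pooling over
#'   positions, then one weight per channel) or `"flatten"` (one weight per
#'   remaining position and channel).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `qcnn`.
#' @export
build_network <- function(spec = network_spec(), quant = quant_scheme(),
                          n_bins = 300L, normalization = c("max", "total"),
                          head = c("gap", "flatten"), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"), inherits(quant, "quant_scheme"))
  normalization <- match.arg(normalization)
  head <- match.arg(head)
  set.seed(as.integer(seed))
  L <- as.integer(n_bins)
  blocks <- vector("list", 4L)
  c_in <- 1L
  for (i in 1:4) {
    b <- spec$blocks[[i]]
    K <- b$kernel; s <- b$stride; f <- b$filters
    P <- (L - K) %/% s + 1L
    if (P < 1L) stop("input too short for the convolution stack", call. = FALSE)
    fan_in <- K * c_in
    blocks[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f),
      bn_gamma = rep(1, f), bn_beta = rep(0, f),
      bn_mean = rep(0, f), bn_var = rep(1, f),
      kernel = K, stride = s, filters = f, in_channels = c_in,
      in_len = L, out_len = P,
      quantized = isTRUE(b$quantized)
    )
    L <- P
    c_in <- f
  }
  n_head_in <- if (head == "gap") c_in else L * c_in
  head_par <- list(
    W = matrix(stats::rnorm(n_head_in, sd = sqrt(1 / n_head_in)),
               n_head_in, 1L),
    b = 0
  )
  structure(list(blocks = blocks, head = head_par, head_type = head,
                 spec = spec, quant = quant, n_bins = as.integer(n_bins),
                 normalization = normalization),
            class = "qcnn")
}

#' @export
print.qcnn <- function(x, ...) {
  cat(sprintf("<qcnn> input %d bins, W_b = %s, A_b = %s, %d parameters%s\n",
              x$n_bins, x$quant$w_bits, x$quant$a_bits, n_parameters(x),
              if (!is.null(x$trained)) " (trained)" else ""))
  invisible(x)
}

# --- internal engine -------------------------------------------------------
# Forward and backward passes live in src/qcnn_engine.cpp (one fused C++
# call per batch; matrix products via BLAS). The R side owns the parameter
# state and the Adam updates.

quant_bits_int <- function(b) if (identical(b, "full")) -1L else as.integer(b)

# evaluation-mode forward pass; X is (B, n_bins) already normalized
qcnn_forward <- function(net, X, train = FALSE, keep_cache = FALSE) {
  pred <- qcnn_predict_cpp(net$blocks, X,
                           quant_bits_int(net$quant$w_bits),
                           quant_bits_int(net$quant$a_bits),
                           as.numeric(net$head$W), net$head$b)
  list(pred = as.numeric(pred))
}

# loss + gradients for one training batch; returns list(loss, grads, net)
# with the net carrying updated batch-norm running statistics
qcnn_backprop <- function(net, X, y, momentum = 0.1) {
  res <- qcnn_train_batch(net$blocks, X, y,
                          quant_bits_int(net$quant$w_bits),
                          quant_bits_int(net$quant$a_bits),
                          as.numeric(net$head$W), net$head$b, momentum)
  for (i in 1:4) {
    net$blocks[[i]]$bn_mean <- as.numeric(res$bn[[i]]$mean)
    net$blocks[[i]]$bn_var <- as.numeric(res$bn[[i]]$var)
  }
  grads <- lapply(res$grads, function(g) {
    list(dW = g$dW, dgamma = as.numeric(g$dgamma), dbeta = as.numeric(g$dbeta))
  })
  list(loss = res$loss, grads = grads,
       dWh = matrix(as.numeric(res$dWh), ncol = 1L), dbh = res$dbh, net = net)
}
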