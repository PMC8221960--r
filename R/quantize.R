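#' Uniform k-bit quantization on [0, 1]
#'
#' The forward quantizer `Q(r, k) = round((2^k - 1) r) / (2^k - 1)`: projects
#' values in `[0, 1]` onto the uniform grid of `2^k` levels. Rounding ties go
#' half away from zero (symmetric treatment of the grid). Inputs outside
#' `[0, 1]` are clipped with a warning — callers are expected to guarantee
#' the range.
#'
#' @param r Numeric vector/array of values in `[0, 1]`.
#' @param k Bit width (integer >= 1).
#' @return Quantized values on the `2^k`-level grid, same shape as `r`.
#' @examples
#' quantize_value(0.3, 2) # 1/3
#' @export
quantize_value <- function(r, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be an integer >= 1", call. = FALSE)
  if (any(r < 0 | r > 1, na.rm = TRUE)) {
    warning("values outside [0, 1] clipped before quantization", call. = FALSE)
    r <- pmin(pmax(r, 0), 1)
  }
  n <- 2^k - 1
  # round half away from zero; arguments are >= 0 here
  floor(n * r + 0.5) / n
}

#' DoReFa-style k-bit weight quantization
#'
#' For `k > 1` weights are squashed with `tanh`, affinely mapped into
#' `[0, 1]` by the layer's maximum magnitude, quantized with
#' [quantize_value()] and mapped back to `[-1, 1]`:
#' `W_k = 2 Q(tanh(W) / (2 max|tanh(W)|) + 1/2, k) - 1`.
#' For `k = 1` the binary special case is used:
#' `W_1 = sign(W) * mean(|W|)` over the layer's weight tensor (so every
#' effective weight takes one of two values, +/- the mean magnitude;
#' `sign(0)` contributes 0).
#'
#' @param W Numeric vector/matrix/array of weights (one layer's tensor).
#' @param k Bit width, or `"full"` for the identity.
#' @return Quantized weights, same shape as `W`.
#' @examples
#' quantize_weights(c(0.2, -0.4), 1) # 0.3, -0.3
#' @export
quantize_weights <- function(W, k) {
  if (identical(k, "full")) return(W)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be an integer >= 1 or \"full\"", call. = FALSE)
  if (k == 1L) {
    scale <- mean(abs(W))
    out <- sign(W) * scale
  } else {
    tw <- tanh(W)
    m <- max(abs(tw))
    if (m == 0) return(W * 0)
    out <- 2 * quantize_value(tw / (2 * m) + 0.5, k) - 1
  }
  out
}

#' DoReFa-style k-bit activation quantization
#'
#' Activations are expected in `[0, 1]` (the preceding batch-normalization
#' and ReLU make that the typical range); a hard clamp to `[0, 1]` is
#' applied before the uniform quantizer, enforcing rather than assuming the
#' precondition.
#'
#' @param A Numeric vector/matrix/array of activations.
#' @param k Bit width, or `"full"` for the identity.
#' @return Quantized activations on the `2^k`-level grid, same shape as `A`.
#' @export
quantize_activations <- function(A, k) {
  if (identical(k, "full")) return(A)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be an integer >= 1 or \"full\"", call. = FALSE)
  Ac <- pmin(pmax(A, 0), 1)
  n <- 2^k - 1
  floor(n * Ac + 0.5) / n
}
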