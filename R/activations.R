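# Self-normalizing constants of the SeLU activation (Klambauer et al.'s
# canonical high-precision values; the 4-decimal forms are 1.6733 / 1.0507).
SELU_BETA <- 1.6732632423543772848170429916717
SELU_LAMBDA <- 1.0507009873554804934193349852946

#' Scaled exponential linear unit (SeLU)
#'
#' Self-normalizing activation: `lambda * x` for `x > 0` and
#' `lambda * beta * (exp(x) - 1)` for `x <= 0`, with the fixed constants
#' `beta ~= 1.6732` and `lambda ~= 1.0507`. With these constants (and
#' suitable weight initialization) activations are driven towards zero
#' mean and unit variance through depth, which is what makes the
#' activation attractive for small, data-poor networks.
#'
#' @param x numeric vector/array of finite values.
#' @return `selu(x)`, same shape as `x`.
#' @examples
#' selu(0)   # 0
#' selu(1)   # ~1.0507
#' @export
selu <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("selu() requires finite numeric input")
  }
  ifelse(x > 0, SELU_LAMBDA * x, SELU_LAMBDA * SELU_BETA * (exp(x) - 1))
}

#' Rectified linear unit
#'
#' `max(0, x)` applied element-wise.
#'
#' @param x numeric vector/array of finite values.
#' @return `pmax(x, 0)`, same shape as `x`.
#' @export
relu <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("relu() requires finite numeric input")
  }
  pmax(x, 0)
}

#' Swish activation
#'
#' `x * sigmoid(x)`, the smooth gating activation used throughout
#' EfficientNet.
#'
#' @param x numeric vector/array.
#' @return `x * sigmoid(x)`.
#' @export
swish <- function(x) x * sigmoid(x)

#' Logistic sigmoid
#'
#' @param x numeric vector/array.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

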