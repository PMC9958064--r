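# Analytic cost accounting: exact integer parameter counts and FLOPs for
# model graphs, plus the standard-vs-depthwise convolution comparison.

#' Cost of a standard convolution layer
#'
#' Multiply count of a dense 2-D convolution producing a `H_F x H_F`
#' output: `H_K^2 * C * C' * H_F^2`.
#'
#' @param kernel_size kernel side `H_K`.
#' @param in_channels,out_channels channel widths `C`, `C'`.
#' @param feature_size output spatial side `H_F`.
#' @return operation count (exact integer arithmetic, as a double).
#' @export
conv_cost <- function(kernel_size, in_channels, out_channels, feature_size) {
  check_cost_spec(kernel_size, in_channels, out_channels, feature_size)
  kernel_size^2 * in_channels * out_channels * feature_size^2
}

#' Cost of a depthwise-separable convolution layer
#'
#' The depthwise stage filters each channel independently and the
#' pointwise stage mixes channels:
#' `H_K^2 * C * H_F^2 + C * C' * H_F^2`.
#'
#' @inheritParams conv_cost
#' @return operation count.
#' @export
separable_cost <- function(kernel_size, in_channels, out_channels,
                           feature_size) {
  check_cost_spec(kernel_size, in_channels, out_channels, feature_size)
  kernel_size^2 * in_channels * feature_size^2 +
    in_channels * out_channels * feature_size^2
}

#' Separable-to-standard convolution cost ratio
#'
#' `separable_cost / conv_cost`, which reduces algebraically to
#' `1/C' + 1/H_K^2`. For a 3x3 kernel the reciprocal (the cost-reduction
#' factor) therefore approaches 9 as the output width grows.
#'
#' @inheritParams conv_cost
#' @return the exact ratio.
#' @export
cost_ratio <- function(kernel_size, in_channels, out_channels, feature_size) {
  separable_cost(kernel_size, in_channels, out_channels, feature_size) /
    conv_cost(kernel_size, in_channels, out_channels, feature_size)
}

check_cost_spec <- function(kernel_size, in_channels, out_channels,
                            feature_size) {
  v <- c(kernel_size, in_channels, out_channels, feature_size)
  if (any(!is.finite(v)) || any(v < 1)) {
    stop("all cost-spec fields must be >= 1")
  }
  invisible(TRUE)
}

#' FLOPs of a convolutional layer
#'
#' `H^2 * (C * K + 1) * C'` where `H` is the post-convolution spatial
#' side, `C` the input channels, `K` the kernel AREA (`k * k`) and `C'`
#' the output channels; the `+ 1` accounts for the bias.
#'
#' @param feature_size output spatial side `H`.
#' @param in_channels input channels `C`.
#' @param kernel_area kernel area `K = k^2`.
#' @param out_channels output channels `C'`.
#' @return FLOPs count.
#' @export
layer_flops <- function(feature_size, in_channels, kernel_area, out_channels) {
  v <- c(feature_size, in_channels, kernel_area, out_channels)
  if (any(!is.finite(v)) || any(v < 1)) stop("all arguments must be >= 1")
  feature_size^2 * (in_channels * kernel_area + 1) * out_channels
}

#' FLOPs of a dense layer
#'
#' `(2I - 1) * O` for `I` inputs and `O` outputs.
#'
#' @param inputs input width `I`.
#' @param outputs output width `O`.
#' @return FLOPs count.
#' @export
dense_flops <- function(inputs, outputs) {
  if (inputs < 1 || outputs < 1) stop("inputs and outputs must be >= 1")
  (2 * inputs - 1) * outputs
}

# Trainable parameters of one node. Batch norm contributes its two
# per-channel affine vectors; running statistics are not trainable.
node_param_count <- function(nd) {
  switch(nd$kind,
    conv = nd$kernel_size^2 * nd$in_channels * nd$out_channels +
      nd$out_channels,
    pwconv = nd$in_channels * nd$out_channels + nd$out_channels,
    dwconv = nd$kernel_size^2 * nd$in_channels * nd$depth_multiplier +
      nd$in_channels * nd$depth_multiplier,
    batchnorm = 2 * nd$out_channels,
    dense = (nd$in_channels + 1) * nd$units,
    0
  )
}

#' Count trainable parameters of a model graph
#'
#' @param graph a `model_graph`.
#' @return total trainable parameter count.
#' @export
count_params <- function(graph) {
  sum(vapply(graph$nodes, node_param_count, 0))
}

#' Profile a model graph: per-layer parameters and FLOPs
#'
#' Applies the convolutional FLOPs formula `H^2 (C K + 1) C'` (with each
#' layer's post-convolution spatial side as `H` and kernel area as `K`)
#' to every convolution, the dense formula `(2I - 1) O` to dense layers,
#' and zero to batch norm, activations, pooling and element-wise
#' add/multiply (the conventions cover only convolution and dense
#' arithmetic). Depthwise convolutions filter one input channel per
#' output channel, so they enter with `C = 1`.
#'
#' @param graph a `model_graph`.
#' @param input_size optional input spatial side overriding the graph's.
#' @return a `flops_report`: list with `layers` (data frame of per-layer
#'   id, kind, output shape, parameters, FLOPs), `conv_flops`,
#'   `dense_flops`, `total_flops` and `params`.
#' @export
profile <- function(graph, input_size = NULL) {
  if (!is.null(input_size)) {
    graph$input_size <- as.integer(input_size)
    validate_graph(graph)
  }
  shapes <- graph_shapes(graph)
  rows <- lapply(graph$nodes, function(nd) {
    sh <- shapes[[nd$id]]
    fl <- switch(nd$kind,
      conv = layer_flops(sh[1], nd$in_channels, nd$kernel_size^2,
                         nd$out_channels),
      pwconv = layer_flops(sh[1], nd$in_channels, 1, nd$out_channels),
      dwconv = layer_flops(sh[1], 1, nd$kernel_size^2,
                           nd$in_channels * nd$depth_multiplier),
      dense = dense_flops(graph$nodes[[nd$id]]$in_channels, nd$units),
      0
    )
    data.frame(id = nd$id, kind = nd$kind,
               out_h = sh[1], out_w = sh[2], out_c = sh[3],
               params = node_param_count(nd), flops = fl,
               stringsAsFactors = FALSE)
  })
  layers <- do.call(rbind, c(rows, make.row.names = FALSE))
  conv_total <- sum(layers$flops[layers$kind %in%
                                   c("conv", "pwconv", "dwconv")])
  dense_total <- sum(layers$flops[layers$kind == "dense"])
  structure(
    list(layers = layers,
         conv_flops = conv_total,
         dense_flops = dense_total,
         total_flops = conv_total + dense_total,
         params = sum(layers$params)),
    class = "flops_report")
}

#' @export
print.flops_report <- function(x, ...) {
  cat("<flops_report> ", nrow(x$layers), " layers\n", sep = "")
  cat(sprintf("  parameters: %s\n", format(x$params, big.mark = ",")))
  cat(sprintf("  FLOPs: %s (conv %s + dense %s) = %.4f GFLOPs\n",
              format(x$total_flops, big.mark = ","),
              format(x$conv_flops, big.mark = ","),
              format(x$dense_flops, big.mark = ","),
              x$total_flops / 1e9))
  invisible(x)
}
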