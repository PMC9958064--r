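# Builders for the network family: MBConv entry blocks, the squeeze-and-
# excitation gate, the truncated CEN backbone, the residual skip block
# (MRSB) and the fused two-branch student.

#' Squeeze-and-excitation gate fragment
#'
#' GAP -> pointwise conv (swish) squeezing to `channels / reduction_ratio`
#' -> pointwise conv (sigmoid) back to `channels` -> element-wise multiply
#' with the block input. The gate re-weights channels by global context.
#'
#' @param channels channels of the gated feature map.
#' @param reduction_ratio squeeze factor (default 4).
#' @return a `graph_fragment`.
#' @export
build_se_block <- function(channels, reduction_ratio = 4L) {
  squeeze <- channels %/% reduction_ratio
  if (squeeze < 1) {
    stop("SE reduction of ", channels, " channels by ", reduction_ratio,
         " leaves fewer than one squeeze channel")
  }
  nodes <- list(
    graph_node("gap", "gap", ".in"),
    graph_node("squeeze", "pwconv", "gap",
               in_channels = channels, out_channels = squeeze),
    graph_node("squeeze_act", "activation", "squeeze", activation = "swish"),
    graph_node("expand", "pwconv", "squeeze_act",
               in_channels = squeeze, out_channels = channels),
    graph_node("gate", "activation", "expand", activation = "sigmoid"),
    graph_node("scale", "multiply", c(".in", "gate"))
  )
  new_fragment(nodes, "scale")
}

#' Entry MBConv block fragment
#'
#' The expansion-free entry block in two variants:
#' `conv 3x3 -> BN -> swish -> dwconv 3x3/1 -> BN -> swish -> SE gate`
#' followed by an element-wise multiply and a final swish. `MBConv-A`
#' downsamples (stride 2 head conv); `MBConv-B` is its stride-1 twin.
#'
#' @param variant `"MBConv-A"` or `"MBConv-B"`.
#' @param in_channels,out_channels channel widths.
#' @param stride head-conv stride; defaults to 2 for A and 1 for B.
#' @param se_reduction squeeze-and-excitation reduction ratio.
#' @return a `graph_fragment`.
#' @export
build_mbconv <- function(variant, in_channels, out_channels, stride = NULL,
                         se_reduction = 4L) {
  if (!variant %in% c("MBConv-A", "MBConv-B")) {
    stop("unknown MBConv variant '", variant, "'")
  }
  if (is.null(stride)) stride <- if (variant == "MBConv-A") 2L else 1L
  nodes <- list(
    graph_node("conv", "conv", ".in", kernel_size = 3L, stride = stride,
               in_channels = in_channels, out_channels = out_channels),
    graph_node("bn1", "batchnorm", "conv",
               in_channels = out_channels, out_channels = out_channels),
    graph_node("act1", "activation", "bn1", activation = "swish"),
    graph_node("dw", "dwconv", "act1", kernel_size = 3L, stride = 1L,
               in_channels = out_channels, out_channels = out_channels),
    graph_node("bn2", "batchnorm", "dw",
               in_channels = out_channels, out_channels = out_channels),
    graph_node("act2", "activation", "bn2", activation = "swish")
  )
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  se <- splice_fragment(build_se_block(out_channels, se_reduction),
                        input_id = "act2", prefix = "se_")
  nodes <- c(nodes, se$nodes)
  nodes[["out"]] <- graph_node("out", "activation", se$output,
                               activation = "swish")
  new_fragment(nodes, "out")
}

#' Modified residual skip block (MRSB) fragment
#'
#' Residual unit `R = F(r) + r` whose main branch is deliberately cheap:
#' a 1x1 depthwise convolution (depth multiplier 1), SeLU, and a 1x1
#' pointwise convolution — no full convolution and no activation after
#' the addition (pre-activation style).
#'
#' @param channels channel width of the residual stream.
#' @return a `graph_fragment`.
#' @export
build_mrsb <- function(channels) {
  if (channels < 1) stop("channels must be >= 1")
  nodes <- list(
    graph_node("dw", "dwconv", ".in", kernel_size = 1L, stride = 1L,
               in_channels = channels, out_channels = channels,
               depth_multiplier = 1L),
    graph_node("act", "activation", "dw", activation = "selu"),
    graph_node("pw", "pwconv", "act",
               in_channels = channels, out_channels = channels),
    graph_node("add", "add", c(".in", "pw"))
  )
  new_fragment(nodes, "add")
}

# Entry-stage plan used when truncating EfficientNetB0: the stem followed
# by alternating downsampling (A) and refining (B) entry MBConv blocks on
# the B0 channel schedule 32 -> 16 -> 24 -> 40 ...
cen_block_plan <- function() {
  list(
    list(variant = "MBConv-A", inc = 32L, outc = 16L, stride = 2L),
    list(variant = "MBConv-B", inc = 16L, outc = 16L, stride = 1L),
    list(variant = "MBConv-A", inc = 16L, outc = 24L, stride = 2L),
    list(variant = "MBConv-B", inc = 24L, outc = 24L, stride = 1L),
    list(variant = "MBConv-A", inc = 24L, outc = 40L, stride = 2L),
    list(variant = "MBConv-B", inc = 40L, outc = 40L, stride = 1L)
  )
}

fragment_param_count <- function(fragment) {
  sum(vapply(fragment$nodes, node_param_count, 0))
}

# The CEN backbone as a fragment: EfficientNetB0 stem plus as many whole
# entry MBConv blocks as fit under the trainable-parameter budget,
# greedily in original order.
cen_fragment <- function(param_budget = 20000L) {
  stem <- list(
    graph_node("stem_conv", "conv", ".in", kernel_size = 3L, stride = 2L,
               in_channels = 3L, out_channels = 32L),
    graph_node("stem_bn", "batchnorm", "stem_conv",
               in_channels = 32L, out_channels = 32L),
    graph_node("stem_act", "activation", "stem_bn", activation = "swish")
  )
  names(stem) <- vapply(stem, `[[`, "", "id")
  nodes <- stem
  total <- sum(vapply(stem, node_param_count, 0))
  out_id <- "stem_act"
  for (i in seq_along(cen_block_plan())) {
    blk <- cen_block_plan()[[i]]
    frag <- build_mbconv(blk$variant, blk$inc, blk$outc, blk$stride)
    cost <- fragment_param_count(frag)
    if (total + cost > param_budget) break
    sp <- splice_fragment(frag, input_id = out_id,
                          prefix = paste0("block", i, "_"))
    nodes <- c(nodes, sp$nodes)
    out_id <- sp$output
    total <- total + cost
  }
  new_fragment(nodes, out_id)
}

#' Build the compressed EfficientNet (CEN) backbone
#'
#' Truncates EfficientNetB0 to its entry feature generators: the stem
#' (conv 3x3/2 -> BN -> swish) followed by whole entry MBConv blocks,
#' kept greedily in original order while total trainable parameters stay
#' within `param_budget` (default 20,000 — the compressed model's budget,
#' down from B0's ~5M).
#'
#' @param input_size input spatial side in pixels (>= 32; default 224).
#' @param seed default weight-initialization seed carried by the graph
#'   and used by [init_model()] when no seed is given there.
#' @param param_budget trainable-parameter ceiling for the truncation.
#' @return a `model_graph` ending in a spatial feature map.
#' @export
build_cen <- function(input_size = 224L, seed = NULL,
                      param_budget = 20000L) {
  if (input_size < 32) {
    stop("input_size ", input_size, " too small for the stride pattern")
  }
  as_model_graph(cen_fragment(param_budget), input_size = input_size,
                 input_channels = 3L, name = "CEN", seed = seed)
}

#' Element-wise feature fusion
#'
#' Adds two equally shaped feature maps element-wise — the fusion step
#' that merges the two backbone branches of the fused student. The
#' operation is commutative and associative, and the zero map is its
#' identity.
#'
#' @param features_a,features_b numeric arrays of identical shape.
#' @return their element-wise sum.
#' @export
fuse <- function(features_a, features_b) {
  da <- dim(features_a) %||% length(features_a)
  db <- dim(features_b) %||% length(features_b)
  if (!identical(da, db)) {
    stop("fuse(): shape mismatch (", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), ")")
  }
  features_a + features_b
}

#' Append a classification head
#'
#' Adds `GAP -> dense(num_classes) -> softmax` to a backbone whose output
#' is a spatial feature map. The dense node is recorded as the graph's
#' `logits` so distillation can read pre-softmax scores.
#'
#' @param backbone a `model_graph`.
#' @param num_classes number of classes (>= 2).
#' @return the extended `model_graph`.
#' @export
attach_head <- function(backbone, num_classes) {
  if (num_classes < 2) stop("num_classes must be >= 2")
  shapes <- graph_shapes(backbone)
  out_shape <- shapes[[backbone$output]]
  channels <- out_shape[3]
  nodes <- backbone$nodes
  nodes[["head_gap"]] <- graph_node("head_gap", "gap", backbone$output)
  nodes[["head_dense"]] <- graph_node("head_dense", "dense", "head_gap",
                                      in_channels = channels,
                                      units = as.integer(num_classes))
  nodes[["head_softmax"]] <- graph_node("head_softmax", "activation",
                                        "head_dense", activation = "softmax")
  g <- backbone
  g$nodes <- nodes
  g$output <- "head_softmax"
  g$logits <- "head_dense"
  validate_graph(g)
  g
}

#' Build the fused student model (FCEN + MRSB + head)
#'
#' Two CEN branches with identical architecture but independent random
#' initializations read the same input; their feature maps are fused by
#' element-wise addition, refined by one MRSB, and classified by a
#' GAP/dense/softmax head.
#'
#' @param input_size input spatial side in pixels (default 224).
#' @param num_classes number of classes (default 6).
#' @param seed default weight-initialization seed carried by the graph.
#' @return a `model_graph` with `logits` set.
#' @export
build_student <- function(input_size = 224L, num_classes = 6L, seed = NULL) {
  if (input_size < 32) {
    stop("input_size ", input_size, " too small for the stride pattern")
  }
  cen <- cen_fragment()
  b1 <- splice_fragment(cen, input_id = "input", prefix = "cen1_")
  b2 <- splice_fragment(cen, input_id = "input", prefix = "cen2_")
  nodes <- c(b1$nodes, b2$nodes)
  nodes[["fuse"]] <- graph_node("fuse", "add", c(b1$output, b2$output))
  mrsb <- splice_fragment(build_mrsb(mrsb_channels(cen)),
                          input_id = "fuse", prefix = "mrsb_")
  nodes <- c(nodes, mrsb$nodes)
  g <- as_model_graph(nodes, input_size = input_size, input_channels = 3L,
                      name = "FCEN-MRSB", output = mrsb$output, seed = seed)
  attach_head(g, num_classes)
}

# Channel width at the output of a CEN fragment.
mrsb_channels <- function(cen) {
  nd <- cen$nodes[[cen$output]]
  while (is.null(nd$out_channels) || nd$kind %in% c("activation", "add",
                                                    "multiply")) {
    nd <- cen$nodes[[nd$inputs[1]]]
  }
  nd$out_channels
}

#' Build a small plain CNN (reference / teacher network)
#'
#' A conventional strided-convolution stack (`conv 3x3/2 -> BN -> swish`
#' per stage) with a GAP/dense/softmax head. Used as a desk-scale teacher
#' for knowledge distillation and as a reference classifier in tests; any
#' trained model exposing logits can play the teacher role.
#'
#' @param input_size input spatial side in pixels.
#' @param num_classes number of classes.
#' @param widths channel widths of the successive stages.
#' @param seed default weight-initialization seed carried by the graph.
#' @return a `model_graph` with `logits` set.
#' @export
build_reference_cnn <- function(input_size, num_classes = 6L,
                                widths = c(24L, 48L, 96L), seed = NULL) {
  nodes <- list()
  inc <- 3L
  prev <- "input"
  for (i in seq_along(widths)) {
    w <- as.integer(widths[i])
    idc <- paste0("s", i, "_conv")
    idb <- paste0("s", i, "_bn")
    ida <- paste0("s", i, "_act")
    nodes[[idc]] <- graph_node(idc, "conv", prev, kernel_size = 3L,
                               stride = 2L, in_channels = inc,
                               out_channels = w)
    nodes[[idb]] <- graph_node(idb, "batchnorm", idc,
                               in_channels = w, out_channels = w)
    nodes[[ida]] <- graph_node(ida, "activation", idb, activation = "swish")
    prev <- ida
    inc <- w
  }
  g <- as_model_graph(nodes, input_size = input_size, input_channels = 3L,
                      name = "reference-cnn", output = prev, seed = seed)
  attach_head(g, num_classes)
}
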