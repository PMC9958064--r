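#' Declare a single layer of a model graph
#'
#' A `layer_spec` is the framework-independent description of one layer:
#' its kind, kernel size, stride, channel widths and activation. Model
#' graphs are ordered collections of these specs plus explicit edges, and
#' everything downstream (instantiation, parameter counting, FLOPs
#' accounting, serialization) works from them.
#'
#' @param kind one of `"conv"`, `"dwconv"`, `"pwconv"`, `"batchnorm"`,
#'   `"activation"`, `"gap"`, `"dense"`, `"add"`, `"multiply"`
#'   (`"sigmoid-gate"` is accepted as an alias for `"multiply"`).
#' @param kernel_size square kernel side in pixels (odd, >= 1).
#' @param stride convolution stride (>= 1).
#' @param in_channels,out_channels channel widths (>= 1). For `dwconv`
#'   the invariant `out_channels == in_channels * depth_multiplier` is
#'   enforced.
#' @param activation `"selu"`, `"swish"`, `"relu"`, `"sigmoid"`,
#'   `"softmax"` or `"none"`.
#' @param depth_multiplier depthwise multiplier Psi (>= 1, `dwconv` only).
#' @param units output width of a `dense` layer.
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(kind,
                       kernel_size = 1L,
                       stride = 1L,
                       in_channels = NULL,
                       out_channels = NULL,
                       activation = "none",
                       depth_multiplier = 1L,
                       units = NULL) {
  kinds <- c("conv", "dwconv", "pwconv", "batchnorm", "activation", "gap",
             "dense", "add", "multiply", "sigmoid-gate", "input")
  if (!kind %in% kinds) stop("unknown layer kind '", kind, "'")
  if (kind == "sigmoid-gate") kind <- "multiply"
  acts <- c("selu", "swish", "relu", "sigmoid", "softmax", "none")
  if (!activation %in% acts) stop("unknown activation '", activation, "'")
  if (kernel_size < 1) stop("kernel_size must be >= 1")
  if (kernel_size %% 2 == 0) stop("only odd kernel sizes are supported")
  if (stride < 1) stop("stride must be >= 1")
  if (!is.null(in_channels) && in_channels < 1) stop("channels must be >= 1")
  if (!is.null(out_channels) && out_channels < 1) stop("channels must be >= 1")
  if (depth_multiplier < 1) stop("depth_multiplier must be >= 1")
  if (kind == "dwconv" && !is.null(in_channels) && !is.null(out_channels) &&
      out_channels != in_channels * depth_multiplier) {
    stop("dwconv requires out_channels == in_channels * depth_multiplier")
  }
  structure(
    list(kind = kind, kernel_size = as.integer(kernel_size),
         stride = as.integer(stride),
         in_channels = if (is.null(in_channels)) NULL else as.integer(in_channels),
         out_channels = if (is.null(out_channels)) NULL else as.integer(out_channels),
         activation = activation,
         depth_multiplier = as.integer(depth_multiplier),
         units = if (is.null(units)) NULL else as.integer(units)),
    class = "layer_spec")
}

# Internal node constructor: a layer_spec plus identity and incoming edges.
graph_node <- function(id, kind, inputs, ...) {
  spec <- layer_spec(kind, ...)
  spec$id <- id
  spec$inputs <- inputs
  spec
}

new_fragment <- function(nodes, output) {
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  structure(list(nodes = nodes, output = output), class = "graph_fragment")
}

#' @export
print.graph_fragment <- function(x, ...) {
  cat("<graph_fragment> ", length(x$nodes), " nodes, output = ",
      x$output, "\n", sep = "")
  invisible(x)
}

# Splice a fragment into a growing node list: prefix local ids, rebind the
# ".in" placeholder to `input_id`, and return the new nodes plus the
# spliced output id.
splice_fragment <- function(fragment, input_id, prefix) {
  nodes <- lapply(fragment$nodes, function(nd) {
    nd$id <- paste0(prefix, nd$id)
    nd$inputs <- vapply(nd$inputs, function(i) {
      if (i == ".in") input_id else paste0(prefix, i)
    }, "")
    nd
  })
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  list(nodes = nodes, output = paste0(prefix, fragment$output))
}

#' Assemble a runnable model graph
#'
#' Wraps ordered graph nodes (or a single fragment) with an input node,
#' producing a `model_graph` that can be instantiated, profiled and
#' serialized.
#'
#' @param x a `graph_fragment` or a named list of nodes.
#' @param input_size input spatial side H in pixels (images are H x H).
#' @param input_channels number of input channels (3 for RGB).
#' @param name graph name.
#' @param output id of the output node (defaults to the fragment output or
#'   the last node).
#' @param logits id of the pre-softmax node, if any.
#' @param seed default weight-initialization seed carried by the graph.
#' @return a `model_graph`.
#' @export
as_model_graph <- function(x, input_size, input_channels = 3L,
                           name = "model", output = NULL, logits = NULL,
                           seed = NULL) {
  if (inherits(x, "graph_fragment")) {
    sp <- splice_fragment(x, "input", "")
    nodes <- sp$nodes
    if (is.null(output)) output <- sp$output
  } else {
    nodes <- x
    if (is.null(output)) output <- nodes[[length(nodes)]]$id
  }
  input_node <- graph_node("input", "input", character())
  g <- structure(
    list(name = name, input_size = as.integer(input_size),
         input_channels = as.integer(input_channels),
         nodes = c(list(input = input_node), nodes),
         output = output, logits = logits, seed = seed),
    class = "model_graph")
  validate_graph(g)
  g
}

validate_graph <- function(graph) {
  seen <- character()
  for (nd in graph$nodes) {
    if (nd$id %in% seen) stop("duplicate node id '", nd$id, "'")
    for (i in nd$inputs) {
      if (!i %in% seen) {
        stop("node '", nd$id, "' references '", i,
             "' before it is defined (graph must be in topological order)")
      }
    }
    seen <- c(seen, nd$id)
  }
  if (!graph$output %in% seen) stop("output node not found")
  # every built graph must propagate shapes consistently
  graph_shapes(graph)
  invisible(graph)
}

#' @export
print.model_graph <- function(x, ...) {
  sh <- graph_shapes(x)
  cat("<model_graph> ", x$name, ": ", length(x$nodes) - 1L, " layers, input ",
      x$input_size, "x", x$input_size, "x", x$input_channels, "\n", sep = "")
  out <- sh[[x$output]]
  cat("  output '", x$output, "': ", paste(out, collapse = "x"), "\n", sep = "")
  invisible(x)
}

conv_out_size <- function(h, k, stride) {
  pad <- (k - 1L) %/% 2L
  out <- (h + 2L * pad - k) %/% stride + 1L
  if (out < 1L) stop("input spatial size ", h, " too small for kernel ", k,
                     " with stride ", stride)
  out
}

#' Propagate shapes through a model graph
#'
#' Computes the output shape `(H, W, C)` of every node from the graph's
#' declared input size, validating edge compatibility on the way. Dense
#' and pooled outputs are reported with `H = W = 1`.
#'
#' @param graph a `model_graph`.
#' @return named list of integer vectors `c(H, W, C)`.
#' @export
graph_shapes <- function(graph) {
  shapes <- list()
  for (nd in graph$nodes) {
    shapes[[nd$id]] <- switch(nd$kind,
      input = c(graph$input_size, graph$input_size, graph$input_channels),
      conv = ,
      pwconv = {
        s <- shapes[[nd$inputs[1]]]
        if (!is.null(nd$in_channels) && s[3] != nd$in_channels) {
          stop("node '", nd$id, "': expects ", nd$in_channels,
               " channels, got ", s[3])
        }
        k <- if (nd$kind == "pwconv") 1L else nd$kernel_size
        h <- conv_out_size(s[1], k, nd$stride)
        c(h, h, nd$out_channels)
      },
      dwconv = {
        s <- shapes[[nd$inputs[1]]]
        if (!is.null(nd$in_channels) && s[3] != nd$in_channels) {
          stop("node '", nd$id, "': expects ", nd$in_channels,
               " channels, got ", s[3])
        }
        h <- conv_out_size(s[1], nd$kernel_size, nd$stride)
        c(h, h, s[3] * nd$depth_multiplier)
      },
      batchnorm = ,
      activation = shapes[[nd$inputs[1]]],
      gap = {
        s <- shapes[[nd$inputs[1]]]
        c(1L, 1L, s[3])
      },
      dense = {
        s <- shapes[[nd$inputs[1]]]
        c(1L, 1L, nd$units)
      },
      add = {
        a <- shapes[[nd$inputs[1]]]
        b <- shapes[[nd$inputs[2]]]
        if (!identical(a, b)) {
          stop("node '", nd$id, "': cannot add shapes ",
               paste(a, collapse = "x"), " and ", paste(b, collapse = "x"))
        }
        a
      },
      multiply = {
        a <- shapes[[nd$inputs[1]]]  # feature map
        b <- shapes[[nd$inputs[2]]]  # per-channel gate
        if (a[3] != b[3] || b[1] != 1L || b[2] != 1L) {
          stop("node '", nd$id, "': gate shape ", paste(b, collapse = "x"),
               " incompatible with features ", paste(a, collapse = "x"))
        }
        a
      },
      stop("unknown node kind '", nd$kind, "'"))
  }
  shapes
}

graph_field_order <- c("id", "kind", "inputs", "kernel_size", "stride",
                       "in_channels", "out_channels", "activation",
                       "depth_multiplier", "units")

#' Write a model graph to a plain-text config file
#'
#' Serializes the ordered layer list (stable field names) as YAML
#' (`.yaml`/`.yml`) or JSON (`.json`). The same files are consumed by
#' [read_model_graph()], [profile()] and the `profile` CLI subcommand.
#'
#' @param graph a `model_graph`.
#' @param path output file path; the extension selects the dialect.
#' @return `path`, invisibly.
#' @export
write_model_graph <- function(graph, path) {
  nodes <- lapply(unname(graph$nodes), function(nd) {
    nd <- nd[graph_field_order]
    nd$inputs <- as.list(nd$inputs)
    nd[!vapply(nd, is.null, TRUE)]
  })
  obj <- list(name = graph$name,
              input_size = graph$input_size,
              input_channels = graph$input_channels,
              output = graph$output,
              logits = graph$logits,
              seed = graph$seed,
              nodes = nodes)
  obj <- obj[!vapply(obj, is.null, TRUE)]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path)
  } else if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    stop("unsupported model graph format '.", ext, "' (use .yaml or .json)")
  }
  invisible(path)
}

#' Read a model graph from a config file
#'
#' @param path a `.yaml`/`.yml` or `.json` file written by
#'   [write_model_graph()] (or by hand, using the same field names).
#' @return a `model_graph`.
#' @export
read_model_graph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("unsupported model graph format '.", ext, "'")
  }
  nodes <- lapply(obj$nodes, function(nd) {
    if (nd$kind == "input") return(graph_node(nd$id, "input", character()))
    graph_node(nd$id, nd$kind, inputs = unlist(nd$inputs),
               kernel_size = nd$kernel_size %||% 1L,
               stride = nd$stride %||% 1L,
               in_channels = nd$in_channels,
               out_channels = nd$out_channels,
               activation = nd$activation %||% "none",
               depth_multiplier = nd$depth_multiplier %||% 1L,
               units = nd$units)
  })
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  nodes <- nodes[names(nodes) != "input"]
  as_model_graph(nodes, input_size = obj$input_size,
                 input_channels = obj$input_channels %||% 3L,
                 name = obj$name %||% "model", output = obj$output,
                 logits = obj$logits, seed = obj$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
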