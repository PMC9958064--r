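# Model-graph executor: weight initialization, forward and backward
# passes, and the Adam optimizer. Feature tensors are H x W x C x N
# arrays; pooled/dense activations are [1,1,C,N] arrays and [units, N]
# matrices respectively (samples in columns throughout the engine).

#' Instantiate a model graph into trainable weights
#'
#' Allocates and initializes every trainable tensor of the graph.
#' Convolution and dense weights use variance-scaling (LeCun normal,
#' `sd = sqrt(1/fan_in)`) draws — the initialization under which SeLU's
#' self-normalizing fixed point holds — with zero biases; batch norm
#' starts at identity (`gamma = 1`, `beta = 0`) with zero/unit running
#' statistics.
#'
#' @param graph a `model_graph`.
#' @param seed integer seed; defaults to the seed carried by the graph.
#'   The same graph and seed always yield bit-identical weights.
#' @return a `cnn_model` (graph + named parameter list).
#' @export
init_model <- function(graph, seed = NULL) {
  seed <- seed %||% graph$seed %||% 1L
  set.seed(seed)
  params <- list()
  for (nd in graph$nodes) {
    params[[nd$id]] <- switch(nd$kind,
      conv = {
        k <- nd$kernel_size
        fan_in <- k^2 * nd$in_channels
        list(W = array(rnorm(k^2 * nd$in_channels * nd$out_channels,
                             sd = sqrt(1 / fan_in)),
                       dim = c(k, k, nd$in_channels, nd$out_channels)),
             b = numeric(nd$out_channels))
      },
      pwconv = {
        fan_in <- nd$in_channels
        list(W = array(rnorm(nd$in_channels * nd$out_channels,
                             sd = sqrt(1 / fan_in)),
                       dim = c(1L, 1L, nd$in_channels, nd$out_channels)),
             b = numeric(nd$out_channels))
      },
      dwconv = {
        k <- nd$kernel_size
        psi <- nd$depth_multiplier
        list(W = array(rnorm(k^2 * nd$in_channels * psi,
                             sd = sqrt(1 / k^2)),
                       dim = c(k, k, nd$in_channels, psi)),
             b = numeric(nd$in_channels * psi))
      },
      dense = {
        list(W = matrix(rnorm(nd$in_channels * nd$units,
                              sd = sqrt(1 / nd$in_channels)),
                        nrow = nd$in_channels, ncol = nd$units),
             b = numeric(nd$units))
      },
      batchnorm = {
        C <- nd$out_channels
        list(gamma = rep(1, C), beta = numeric(C),
             run_mean = numeric(C), run_var = rep(1, C))
      },
      NULL
    )
  }
  structure(list(graph = graph, params = params, seed = seed),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> ", x$graph$name, " (seed ", x$seed, "), ",
      format(count_params(x$graph), big.mark = ","),
      " trainable parameters\n", sep = "")
  invisible(x)
}

# Integer codes shared with the C++ activation kernels.
act_kind <- function(name) {
  switch(name, swish = 0L, sigmoid = 1L, selu = 2L, relu = 3L,
         stop("unknown activation '", name, "'"))
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

# Forward pass. Returns final output, logits and per-node caches needed
# by the backward pass.
forward_pass <- function(model, x, train = TRUE) {
  g <- model$graph
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[1] == g$input_size, dim(x)[3] == g$input_channels)
  cache <- list()
  for (nd in g$nodes) {
    p <- model$params[[nd$id]]
    out <- switch(nd$kind,
      input = x,
      conv = ,
      pwconv = cpp_conv_fwd(cache[[nd$inputs[1]]]$out, p$W, p$b, nd$stride),
      dwconv = cpp_dwconv_fwd(cache[[nd$inputs[1]]]$out, p$W, p$b, nd$stride),
      batchnorm = {
        xin <- cache[[nd$inputs[1]]]$out
        d <- dim(xin)
        if (train) {
          m <- d[1] * d[2] * d[4]
          s <- cpp_channel_sums2(xin, xin)
          mu <- s[, 1] / m
          vr <- s[, 2] / m - mu^2
          model$params[[nd$id]]$run_mean <-
            BN_MOMENTUM * p$run_mean + (1 - BN_MOMENTUM) * mu
          model$params[[nd$id]]$run_var <-
            BN_MOMENTUM * p$run_var + (1 - BN_MOMENTUM) * vr
        } else {
          mu <- p$run_mean
          vr <- p$run_var
        }
        inv_std <- 1 / sqrt(vr + BN_EPS)
        # y = x * a + b with per-channel a, b (folds normalize + affine)
        a <- p$gamma * inv_std
        y <- cpp_scale_shift(xin, a, p$beta - a * mu)
        if (train) {
          xhat <- cpp_scale_shift(xin, inv_std, -inv_std * mu)
          cache[[nd$id]] <- list(xhat = xhat, inv_std = inv_std, dims = d)
        }
        y
      },
      activation = {
        xin <- cache[[nd$inputs[1]]]$out
        if (nd$activation == "softmax") col_softmax(xin) else
          cpp_act_fwd(xin, act_kind(nd$activation))
      },
      gap = {
        xin <- cache[[nd$inputs[1]]]$out
        d <- dim(xin)
        m <- colMeans(matrix(xin, nrow = d[1] * d[2]))
        array(m, dim = c(1L, 1L, d[3], d[4]))
      },
      dense = {
        xin <- cache[[nd$inputs[1]]]$out
        xmat <- flatten_cn(xin)
        crossprod(p$W, xmat) + p$b
      },
      add = cache[[nd$inputs[1]]]$out + cache[[nd$inputs[2]]]$out,
      multiply = cpp_gate_fwd(cache[[nd$inputs[1]]]$out,
                              cache[[nd$inputs[2]]]$out)
    )
    cache[[nd$id]]$out <- out
  }
  logits <- if (!is.null(g$logits)) cache[[g$logits]]$out else NULL
  # `model` is returned because training-mode batch norm updates its
  # running statistics.
  list(out = cache[[g$output]]$out, logits = logits, cache = cache,
       model = model)
}

# [1,1,C,N] array (or matrix) -> C x N matrix.
flatten_cn <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(x, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

# Column-wise numerically stabilized softmax over a [C, N] matrix (or a
# [1,1,C,N] array, returned as a matrix).
col_softmax <- function(x) {
  x <- flatten_cn(x)
  x <- sweep(x, 2, apply(x, 2, max))
  e <- exp(x)
  sweep(e, 2, colSums(e), `/`)
}

# Backward pass from a gradient at the logits node. Returns per-node
# parameter gradients. Nodes downstream of the logits node (the softmax
# output) carry no gradient.
backward_pass <- function(model, cache, dlogits) {
  g <- model$graph
  nodes <- g$nodes
  dout <- list()
  dout[[g$logits]] <- dlogits
  grads <- list()
  acc <- function(id, val) {
    if (is.null(dout[[id]])) val else dout[[id]] + val
  }
  for (nd in rev(nodes)) {
    dy <- dout[[nd$id]]
    if (is.null(dy) || nd$kind == "input") next
    p <- model$params[[nd$id]]
    inps <- nd$inputs
    switch(nd$kind,
      conv = ,
      pwconv = {
        bw <- cpp_conv_bwd(cache[[inps[1]]]$out, p$W, dy, nd$stride)
        grads[[nd$id]] <- list(W = bw$dw, b = bw$db)
        dout[[inps[1]]] <- acc(inps[1], bw$dx)
      },
      dwconv = {
        bw <- cpp_dwconv_bwd(cache[[inps[1]]]$out, p$W, dy, nd$stride)
        grads[[nd$id]] <- list(W = bw$dw, b = bw$db)
        dout[[inps[1]]] <- acc(inps[1], bw$dx)
      },
      batchnorm = {
        cc <- cache[[nd$id]]
        d <- cc$dims
        m <- d[1] * d[2] * d[4]
        s <- cpp_channel_sums2(dy, cc$xhat)
        grads[[nd$id]] <- list(gamma = s[, 2], beta = s[, 1])
        a <- p$gamma * cc$inv_std
        dx <- cpp_bn_bwd_dx(dy, cc$xhat, a, a * s[, 1] / m, a * s[, 2] / m)
        dout[[inps[1]]] <- acc(inps[1], dx)
      },
      activation = {
        if (nd$activation == "softmax") {
          stop("backward pass reached a softmax node; compute loss ",
               "gradients at the logits instead")
        }
        xin <- cache[[inps[1]]]$out
        dx <- cpp_act_bwd(xin, dy, act_kind(nd$activation))
        dout[[inps[1]]] <- acc(inps[1], dx)
      },
      gap = {
        xin <- cache[[inps[1]]]$out
        d <- dim(xin)
        dx <- cpp_gap_bwd(dy, d[1], d[2])
        dout[[inps[1]]] <- acc(inps[1], dx)
      },
      dense = {
        xmat <- flatten_cn(cache[[inps[1]]]$out)
        grads[[nd$id]] <- list(W = xmat %*% t(dy), b = rowSums(dy))
        dx <- p$W %*% dy
        din <- cache[[inps[1]]]$out
        if (!is.matrix(din)) dim(dx) <- dim(din)
        dout[[inps[1]]] <- acc(inps[1], dx)
      },
      add = {
        dout[[inps[1]]] <- acc(inps[1], dy)
        dout[[inps[2]]] <- acc(inps[2], dy)
      },
      multiply = {
        bw <- cpp_gate_bwd(cache[[inps[1]]]$out, cache[[inps[2]]]$out, dy)
        dout[[inps[1]]] <- acc(inps[1], bw$dx)
        dout[[inps[2]]] <- acc(inps[2], bw$dg)
      }
    )
    dout[[nd$id]] <- NULL  # free
  }
  grads
}

adam_init <- function() {
  structure(list(state = list(), t = 0L), class = "adam_state")
}

adam_step <- function(model, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (id in names(grads)) {
    for (nm in names(grads[[id]])) {
      gr <- grads[[id]][[nm]]
      key <- paste0(id, ".", nm)
      st <- opt$state[[key]]
      if (is.null(st)) st <- list(m = gr * 0, v = gr * 0)
      st$m <- beta1 * st$m + (1 - beta1) * gr
      st$v <- beta2 * st$v + (1 - beta2) * gr^2
      opt$state[[key]] <- st
      upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      model$params[[id]][[nm]] <- model$params[[id]][[nm]] - upd
    }
  }
  list(model = model, opt = opt)
}

#' Logits of a model on a batch of images
#'
#' Runs the model in inference mode (batch norm uses running statistics)
#' and returns the pre-softmax class scores.
#'
#' @param model a `cnn_model` or a fit returned by [train_classifier()]
#'   or [distill()].
#' @param images `H x W x C x N` array (or a single `H x W x C` image).
#' @param batch_size inference batch size.
#' @return `N x num_classes` matrix of logits (samples in rows).
#' @export
model_logits <- function(model, images, batch_size = 64L) {
  model <- as_cnn_model(model)
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4]
  pieces <- lapply(split(seq_len(n), ceiling(seq_len(n) / batch_size)),
                   function(idx) {
                     fw <- forward_pass(model, images[, , , idx, drop = FALSE],
                                        train = FALSE)
                     t(fw$logits)
                   })
  do.call(rbind, pieces)
}

#' Predicted classes of a model on a batch of images
#'
#' @inheritParams model_logits
#' @return integer vector of 1-based class indices.
#' @export
predict_classes <- function(model, images, batch_size = 64L) {
  lg <- model_logits(model, images, batch_size)
  max.col(lg, ties.method = "first")
}

as_cnn_model <- function(x) {
  if (inherits(x, "cnn_model")) return(x)
  if (inherits(x, "cenkd_fit")) return(x$model)
  stop("expected a cnn_model or cenkd_fit")
}
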