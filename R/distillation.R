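# Knowledge distillation: temperature-scaled softmax, the soft (KL) and
# hard (cross-entropy) losses, their weighted combination, and the two
# training entry points (plain supervised training and teacher->student
# distillation).

#' Knowledge-distillation / training configuration
#'
#' Hyper-parameters shared by [train_classifier()] and [distill()].
#' Defaults follow the method's published settings: temperature 2,
#' balance 0.3, Adam, batch size 16, 30 epochs. The learning rate
#' defaults to 0.0001 for plain training and 0.001 for the distillation
#' stage; leave it `NULL` to get the stage-appropriate default.
#'
#' @param temperature softmax temperature tau (> 0).
#' @param alpha balance between hard loss (weight `alpha`) and soft loss
#'   (weight `1 - alpha`), in `[0, 1]`.
#' @param learning_rate Adam learning rate, or `NULL` for the stage
#'   default.
#' @param batch_size mini-batch size.
#' @param epochs number of training epochs.
#' @param optimizer optimizer name (only `"adam"` is implemented).
#' @param seed seed controlling shuffling (and weight init when the
#'   graph carries none).
#' @return a `kd_config` list.
#' @export
kd_config <- function(temperature = 2, alpha = 0.3, learning_rate = NULL,
                      batch_size = 16L, epochs = 30L, optimizer = "adam",
                      seed = 1L) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  structure(list(temperature = temperature, alpha = alpha,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "kd_config")
}

#' Temperature-scaled softmax
#'
#' Softmax of `logits / tau`, numerically stabilized by a max shift.
#' `tau = 1` recovers the standard softmax; `tau > 1` softens the
#' distribution (smaller max-min probability gap), which is what exposes
#' the teacher's "dark knowledge" about class similarity during
#' distillation.
#'
#' @param logits numeric vector of per-class scores, or a matrix with
#'   samples in rows and classes in columns.
#' @param tau temperature (> 0).
#' @return probabilities of the same shape, each (row) summing to 1.
#' @export
tempered_softmax <- function(logits, tau = 1) {
  if (tau <= 0) stop("tau must be > 0")
  if (is.matrix(logits)) {
    z <- logits / tau
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- logits / tau
    e <- exp(z - max(z))
    e / sum(e)
  }
}

PROB_EPS <- 1e-12

#' Soft loss: KL divergence between teacher and student distributions
#'
#' `KL(teacher || student)` summed over classes (natural log), with the
#' student clamped at `1e-12`. For matrices (samples in rows) the mean
#' over samples is returned.
#'
#' @param teacher,student probability vectors (or matrices, samples in
#'   rows) of matching shape.
#' @return nonnegative scalar.
#' @export
soft_loss <- function(teacher, student) {
  if (length(teacher) != length(student)) {
    stop("soft_loss(): teacher and student lengths differ")
  }
  s <- pmax(student, PROB_EPS)
  term <- ifelse(teacher > 0, teacher * (log(teacher) - log(s)), 0)
  if (is.matrix(teacher)) mean(rowSums(term)) else sum(term)
}

#' Hard loss: categorical cross-entropy against ground-truth labels
#'
#' `-log(prediction[label])` (natural log, predictions clamped at
#' `1e-12`); for a batch (matrix predictions, vector of labels) the mean
#' over samples.
#'
#' @param predictions probability vector, or matrix with samples in rows.
#' @param label 1-based true class index (vector for a batch).
#' @return nonnegative scalar.
#' @export
hard_loss <- function(predictions, label) {
  if (is.matrix(predictions)) {
    if (length(label) != nrow(predictions)) {
      stop("hard_loss(): one label per row is required")
    }
    if (any(label < 1 | label > ncol(predictions))) {
      stop("hard_loss(): label index out of range")
    }
    p <- pmax(predictions[cbind(seq_len(nrow(predictions)), label)], PROB_EPS)
    mean(-log(p))
  } else {
    if (length(label) != 1 || label < 1 || label > length(predictions)) {
      stop("hard_loss(): label index out of range")
    }
    -log(max(predictions[label], PROB_EPS))
  }
}

#' Total distillation loss
#'
#' `soft * (1 - alpha) + hard * alpha`: `alpha = 1` reduces to plain
#' supervised training, `alpha = 0` to pure imitation of the teacher.
#'
#' @param soft soft-loss value.
#' @param hard hard-loss value.
#' @param alpha balance in `[0, 1]`.
#' @return the weighted sum.
#' @export
total_loss <- function(soft, hard, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  soft * (1 - alpha) + hard * alpha
}

# Shared scaffolding for both trainers: resolve the training split,
# labels and one-hot targets.
training_arrays <- function(data, graph) {
  stopifnot(inherits(data, "image_dataset"))
  man <- data$manifest
  idx <- if (all(is.na(man$split))) seq_len(nrow(man)) else
    which(man$split == "train")
  labels <- match(man$class[idx], data$classes)
  ncls <- length(data$classes)
  counts <- tabulate(labels, nbins = ncls)
  if (any(counts == 0)) {
    stop("class '", data$classes[which(counts == 0)[1]],
         "' has no training samples")
  }
  head_units <- graph$nodes[[graph$logits]]$units
  if (!is.null(head_units) && head_units != ncls) {
    stop("model head width (", head_units, ") does not match class count (",
         ncls, ")")
  }
  if (dim(data$images)[1] != graph$input_size) {
    stop("dataset image size ", dim(data$images)[1],
         " does not match graph input size ", graph$input_size)
  }
  onehot <- matrix(0, ncls, length(idx))
  onehot[cbind(labels, seq_along(labels))] <- 1
  list(idx = idx, labels = labels, onehot = onehot, n_classes = ncls)
}

#' Train a classifier with plain supervised learning
#'
#' Standard categorical cross-entropy training with the configured
#' optimizer on the dataset's training split. This is both the teacher
#' training stage and the non-distilled ("non-KD") student baseline.
#'
#' @param graph a `model_graph` with a softmax head (see
#'   [attach_head()]), or an already initialized `cnn_model` to continue.
#' @param data an `image_dataset` (see [synthesize_dataset()],
#'   [load_image_folder()]); samples tagged `train` are used, or all
#'   samples when no split is assigned.
#' @param config a [kd_config()]; the learning rate defaults to 0.0001.
#' @return a `cenkd_fit`: list with the trained `model`, a per-epoch
#'   `history` data frame (loss, training accuracy) and the `config`.
#' @export
train_classifier <- function(graph, data, config = kd_config()) {
  lr <- config$learning_rate %||% 1e-4
  is_model <- inherits(graph, "cnn_model")
  g <- if (is_model) graph$graph else graph
  arr <- training_arrays(data, g)
  set.seed(config$seed)
  model <- if (is_model) graph else init_model(g, seed = g$seed %||% config$seed)
  opt <- adam_init()
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(arr$idx))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    ep_correct <- 0L
    for (bi in batches) {
      xb <- data$images[, , , arr$idx[bi], drop = FALSE]
      fw <- forward_pass(model, xb, train = TRUE)
      model <- fw$model
      probs <- col_softmax(fw$logits)
      yb <- arr$onehot[, bi, drop = FALSE]
      ep_loss <- ep_loss + hard_loss(t(probs), arr$labels[bi]) * length(bi)
      ep_correct <- ep_correct + sum(max.col(t(probs)) == arr$labels[bi])
      dlogits <- (probs - yb) / length(bi)
      grads <- backward_pass(model, fw$cache, dlogits)
      st <- adam_step(model, grads, opt, lr)
      model <- st$model
      opt <- st$opt
    }
    history[[epoch]] <- data.frame(epoch = epoch,
                                   loss = ep_loss / length(arr$idx),
                                   accuracy = ep_correct / length(arr$idx))
  }
  structure(list(model = model, history = do.call(rbind, history),
                 config = config),
            class = "cenkd_fit")
}

#' Train a student by knowledge distillation
#'
#' The teacher is frozen; its logits over the training split are computed
#' once. Each batch then forms soft targets (teacher logits through the
#' temperature-`tau` softmax), soft predictions (student logits through
#' the same tempered softmax), and hard predictions (student logits at
#' `tau = 1`), and optimizes
#' `total = soft_kl * (1 - alpha) + hard_cce * alpha`. Gradients flow
#' only through the student.
#'
#' @param teacher a trained model (`cenkd_fit` or `cnn_model`) whose head
#'   width matches the student's.
#' @param student_graph the student's `model_graph` (or `cnn_model`).
#' @param data an `image_dataset`.
#' @param config a [kd_config()]; the learning rate defaults to 0.001.
#' @return a `cenkd_fit` whose `history` has per-epoch soft, hard and
#'   total losses plus training accuracy.
#' @export
distill <- function(teacher, student_graph, data, config = kd_config()) {
  lr <- config$learning_rate %||% 1e-3
  tau <- config$temperature
  alpha <- config$alpha
  is_model <- inherits(student_graph, "cnn_model")
  g <- if (is_model) student_graph$graph else student_graph
  arr <- training_arrays(data, g)
  tmodel <- as_cnn_model(teacher)
  t_units <- tmodel$graph$nodes[[tmodel$graph$logits]]$units
  s_units <- g$nodes[[g$logits]]$units
  if (!identical(t_units, s_units)) {
    stop("teacher emits ", t_units, " logits but student emits ", s_units)
  }
  teacher_logits <- t(model_logits(tmodel, data$images[, , , arr$idx,
                                                       drop = FALSE]))
  set.seed(config$seed)
  model <- if (is_model) student_graph else
    init_model(g, seed = g$seed %||% config$seed)
  opt <- adam_init()
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(arr$idx))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep <- c(soft = 0, hard = 0, correct = 0)
    for (bi in batches) {
      xb <- data$images[, , , arr$idx[bi], drop = FALSE]
      fw <- forward_pass(model, xb, train = TRUE)
      model <- fw$model
      t_soft <- col_softmax(teacher_logits[, bi, drop = FALSE] / tau)
      s_soft <- col_softmax(fw$logits / tau)
      probs <- col_softmax(fw$logits)
      yb <- arr$onehot[, bi, drop = FALSE]
      ep["soft"] <- ep["soft"] + soft_loss(t(t_soft), t(s_soft)) * length(bi)
      ep["hard"] <- ep["hard"] + hard_loss(t(probs), arr$labels[bi]) * length(bi)
      ep["correct"] <- ep["correct"] +
        sum(max.col(t(probs)) == arr$labels[bi])
      dlogits <- ((1 - alpha) * (s_soft - t_soft) / tau +
                    alpha * (probs - yb)) / length(bi)
      grads <- backward_pass(model, fw$cache, dlogits)
      st <- adam_step(model, grads, opt, lr)
      model <- st$model
      opt <- st$opt
    }
    n <- length(arr$idx)
    history[[epoch]] <- data.frame(
      epoch = epoch, soft_loss = ep[["soft"]] / n,
      hard_loss = ep[["hard"]] / n,
      total_loss = total_loss(ep[["soft"]] / n, ep[["hard"]] / n, alpha),
      accuracy = ep[["correct"]] / n)
  }
  structure(list(model = model, history = do.call(rbind, history),
                 config = config, teacher = NULL),
            class = "cenkd_fit")
}

#' @export
print.cenkd_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<cenkd_fit> ", x$model$graph$name, ": ", nrow(x$history),
      " epochs, final training accuracy ",
      sprintf("%.3f", last$accuracy), "\n", sep = "")
  invisible(x)
}
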