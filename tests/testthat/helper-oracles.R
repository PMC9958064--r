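# Independent oracles used across tests. These deliberately avoid the
# package's analytic code paths: parameters are counted by measuring the
# instantiated weight tensors, FLOPs are recomputed from the tensors and
# the spatial sizes observed during an actual forward pass, and metrics
# are tallied by exhaustive TP/TN/FP/FN enumeration.

# Count trainable parameters by measuring every instantiated tensor
# (running batch-norm statistics are not trainable).
enumerate_params <- function(graph, seed = 1L) {
  m <- init_model(graph, seed = seed)
  total <- 0
  for (p in m$params) {
    for (nm in intersect(names(p), c("W", "b", "gamma", "beta"))) {
      total <- total + length(p[[nm]])
    }
  }
  total
}

# Recompute total FLOPs layer by layer from executed output shapes and
# weight-tensor dimensions.
enumerate_flops <- function(graph, seed = 1L) {
  m <- init_model(graph, seed = seed)
  x <- array(0.5, dim = c(graph$input_size, graph$input_size,
                          graph$input_channels, 1L))
  fw <- cenkd:::forward_pass(m, x, train = FALSE)
  total <- 0
  for (nd in graph$nodes) {
    p <- m$params[[nd$id]]
    if (is.null(p$W)) next
    out <- fw$cache[[nd$id]]$out
    dW <- dim(p$W)
    if (nd$kind %in% c("conv", "pwconv")) {
      h <- dim(out)[1]
      total <- total + h^2 * (dW[3] * dW[1] * dW[2] + 1) * dW[4]
    } else if (nd$kind == "dwconv") {
      h <- dim(out)[1]
      total <- total + h^2 * (dW[1] * dW[2] + 1) * (dW[3] * dW[4])
    } else if (nd$kind == "dense") {
      total <- total + (2 * nrow(p$W) - 1) * ncol(p$W)
    }
  }
  total
}

# Exhaustive one-vs-rest tally for one class of a confusion matrix.
brute_force_class_counts <- function(cm, cls) {
  tp <- fp <- fn <- tn <- 0L
  n <- nrow(cm)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cnt <- cm[i, j]
      if (i == cls && j == cls) tp <- tp + cnt
      else if (j == cls) fp <- fp + cnt
      else if (i == cls) fn <- fn + cnt
      else tn <- tn + cnt
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

brute_force_metrics <- function(cm) {
  n <- nrow(cm)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("acc", "pr", "rc", "f1")))
  for (cls in seq_len(n)) {
    cnt <- brute_force_class_counts(cm, cls)
    all <- sum(cnt)
    out[cls, "acc"] <- 100 * (cnt["tp"] + cnt["tn"]) / all
    if (cnt["tp"] + cnt["fp"] > 0) {
      out[cls, "pr"] <- 100 * cnt["tp"] / (cnt["tp"] + cnt["fp"])
    }
    if (cnt["tp"] + cnt["fn"] > 0) {
      out[cls, "rc"] <- 100 * cnt["tp"] / (cnt["tp"] + cnt["fn"])
    }
    pr <- out[cls, "pr"]; rc <- out[cls, "rc"]
    if (!is.na(pr) && !is.na(rc) && pr + rc > 0) {
      out[cls, "f1"] <- 2 * pr * rc / (pr + rc)
    }
  }
  out
}

# A six-class mosquito-style validation tally (765 samples) whose
# per-class precision/recall reproduce a published-style report; used as
# a worked example for the metrics math.
mosquito_confusion <- function() {
  classes <- c("Non-Vector", "Aedes albopictus", "Aedes vexans",
               "Anopheles sinensis", "Culex pipiens",
               "Culex tritaeniorhynchus")
  cm <- diag(c(120L, 118L, 118L, 105L, 179L, 119L))
  cm[2, 3] <- 1L  # albopictus -> vexans
  cm[2, 6] <- 1L  # albopictus -> tritaeniorhynchus
  cm[4, 3] <- 2L  # sinensis -> vexans
  cm[4, 6] <- 1L  # sinensis -> tritaeniorhynchus
  cm[5, 6] <- 1L  # pipiens -> tritaeniorhynchus
  rownames(cm) <- colnames(cm) <- classes
  cm
}

# Small quick dataset for training tests.
tiny_dataset <- function(per_class = 8, noise = 0, seed = 1,
                         image_size = 32, split = TRUE) {
  ds <- synthesize_dataset(synth_spec(classes = 6, per_class = per_class,
                                      image_size = image_size,
                                      noise = noise, seed = seed))
  if (split) ds <- split_dataset(ds, 0.8, seed = seed)
  ds
}

# Minimal batchnorm-free classifier graph (identical behaviour in train
# and eval mode), handy when a test needs train/eval equivalence.
plain_graph <- function(input_size = 32, num_classes = 6, channels = 8,
                        seed = 1) {
  nodes <- list(
    conv1 = cenkd:::graph_node("conv1", "conv", "input", kernel_size = 3L,
                               stride = 2L, in_channels = 3L,
                               out_channels = channels),
    act1 = cenkd:::graph_node("act1", "activation", "conv1",
                              activation = "swish"),
    conv2 = cenkd:::graph_node("conv2", "conv", "act1", kernel_size = 3L,
                               stride = 2L, in_channels = channels,
                               out_channels = 2L * channels),
    act2 = cenkd:::graph_node("act2", "activation", "conv2",
                              activation = "swish")
  )
  g <- as_model_graph(nodes, input_size = input_size, input_channels = 3L,
                      name = "plain-cnn", seed = seed)
  attach_head(g, num_classes)
}
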