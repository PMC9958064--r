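# Confusion-matrix metrics: per-class one-vs-rest accuracy, precision,
# recall, F1 (reported as percent, half-up to 2 decimals) and the
# count-weighted overall row, plus the end-to-end evaluate() driver.

# Base round() is banker's rounding; printed tables use half-up.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes (1-based indices or
#' factors with shared levels).
#'
#' @param truth,predicted equal-length label vectors.
#' @param n_classes number of classes; inferred from the data (or factor
#'   levels) when omitted.
#' @return an `n x n` integer matrix.
#' @export
confusion <- function(truth, predicted, n_classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop("confusion(): truth and predicted lengths differ")
  }
  if (is.factor(truth) || is.factor(predicted)) {
    levs <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
    truth <- match(as.character(truth), levs)
    predicted <- match(as.character(predicted), levs)
    if (is.null(n_classes)) n_classes <- length(levs)
  }
  if (is.null(n_classes)) n_classes <- max(truth, predicted)
  if (any(truth < 1 | truth > n_classes) ||
      any(predicted < 1 | predicted > n_classes)) {
    stop("labels must lie in 1..n_classes")
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    cm[truth[i], predicted[i]] <- cm[truth[i], predicted[i]] + 1L
  }
  cm
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * Pr * Rc / (Pr + Rc)`; works on either the percent
#' or the proportion scale.
#'
#' @param precision,recall precision and recall values.
#' @return the F1 score on the same scale.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
         2 * precision * recall / (precision + recall))
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class `c` (one-vs-rest over ALL evaluated samples):
#' `TP = cm[c,c]`, `FP` = rest of column, `FN` = rest of row, `TN` =
#' everything else; then `Acc = (TP+TN)/all`, `Pr = TP/(TP+FP)`,
#' `Rc = TP/(TP+FN)`, `F1 = 2 Pr Rc/(Pr+Rc)`. Values are percentages
#' rounded half-up to 2 decimals in `$per_class`; unrounded values are
#' kept in `$exact` and used for overall aggregation. Zero denominators
#' yield `NA` ("undefined") with a warning rather than 0.
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @return a `metrics_report`: list with `per_class` (rounded percent),
#'   `exact` (unrounded percent), `counts` (per-class true counts),
#'   `total` and `correct`.
#' @export
per_class_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0) {
    stop("per_class_metrics() expects a nonempty square confusion matrix")
  }
  n <- nrow(cm)
  total <- sum(cm)
  classes <- rownames(cm) %||% sprintf("class%02d", seq_len(n))
  exact <- data.frame(class = classes, n = rowSums(cm),
                      accuracy = NA_real_, precision = NA_real_,
                      recall = NA_real_, f1 = NA_real_,
                      stringsAsFactors = FALSE, row.names = NULL)
  undefined <- character()
  for (c in seq_len(n)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    tn <- total - tp - fp - fn
    exact$accuracy[c] <- 100 * (tp + tn) / total
    exact$precision[c] <- if (tp + fp == 0) NA_real_ else
      100 * tp / (tp + fp)
    exact$recall[c] <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
    exact$f1[c] <- if (is.na(exact$precision[c]) || is.na(exact$recall[c]) ||
                       exact$precision[c] + exact$recall[c] == 0) NA_real_
      else f1_score(exact$precision[c], exact$recall[c])
    if (anyNA(exact[c, c("precision", "recall", "f1")])) {
      undefined <- c(undefined, classes[c])
    }
  }
  if (length(undefined) > 0) {
    warning("metrics undefined (zero denominator) for class(es): ",
            paste(undefined, collapse = ", "))
  }
  rounded <- exact
  for (col in c("accuracy", "precision", "recall", "f1")) {
    rounded[[col]] <- round_half_up(exact[[col]])
  }
  structure(list(per_class = rounded, exact = exact,
                 counts = rowSums(cm), total = total,
                 correct = sum(diag(cm))),
            class = "metrics_report")
}

#' Overall (count-weighted) metrics row
#'
#' Overall precision, recall and F1 are the validation-count-weighted
#' means of the unrounded per-class values; overall accuracy is total
#' correct over total samples. With exact per-class values this
#' weighting makes overall recall coincide with overall accuracy
#' (micro averaging). An unweighted (macro) mean is available via
#' `weighted = FALSE`.
#'
#' @param report a `metrics_report` from [per_class_metrics()].
#' @param weighted use count weights (default) or a plain mean.
#' @return one-row data frame (`n`, `accuracy`, `precision`, `recall`,
#'   `f1`, percent, rounded half-up to 2 decimals).
#' @export
overall_metrics <- function(report, weighted = TRUE) {
  stopifnot(inherits(report, "metrics_report"))
  ex <- report$exact
  w <- if (weighted) report$counts else rep(1, nrow(ex))
  wmean <- function(v) {
    ok <- !is.na(v)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  data.frame(class = "Overall", n = report$total,
             accuracy = round_half_up(100 * report$correct / report$total),
             precision = round_half_up(wmean(ex$precision)),
             recall = round_half_up(wmean(ex$recall)),
             f1 = round_half_up(wmean(ex$f1)),
             stringsAsFactors = FALSE)
}

#' @export
print.metrics_report <- function(x, ...) {
  tab <- rbind(x$per_class, overall_metrics(x))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Evaluate a trained model on a dataset's validation split
#'
#' Runs inference on the validation samples, tallies the confusion
#' matrix, computes per-class and overall metrics, and attaches the
#' analytic cost profile of the model graph.
#'
#' @param model a `cnn_model` or `cenkd_fit`.
#' @param dataset an `image_dataset` with an assigned split (see
#'   [split_dataset()]).
#' @param batch_size inference batch size.
#' @return list with `metrics` (a `metrics_report`), `overall` (one-row
#'   data frame), `confusion`, `accuracy` (proportion correct) and
#'   `cost` (a `flops_report`).
#' @export
evaluate <- function(model, dataset, batch_size = 64L) {
  stopifnot(inherits(dataset, "image_dataset"))
  mdl <- as_cnn_model(model)
  idx <- which(dataset$manifest$split == "validation")
  if (length(idx) == 0) stop("dataset has no validation samples")
  ncls <- length(dataset$classes)
  units <- mdl$graph$nodes[[mdl$graph$logits]]$units
  if (!is.null(units) && units != ncls) {
    stop("model head width (", units, ") does not match class count (",
         ncls, ")")
  }
  truth <- match(dataset$manifest$class[idx], dataset$classes)
  pred <- predict_classes(mdl, dataset$images[, , , idx, drop = FALSE],
                          batch_size = batch_size)
  cm <- confusion(truth, pred, ncls)
  rownames(cm) <- colnames(cm) <- dataset$classes
  metrics <- per_class_metrics(cm)
  list(metrics = metrics, overall = overall_metrics(metrics),
       confusion = cm, accuracy = metrics$correct / metrics$total,
       cost = profile(mdl$graph))
}
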