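test_that("confusion tallies counts with rows as truth", {
  cm <- confusion(c(1, 2, 3), c(1, 2, 3), 3)
  expect_identical(cm, diag(c(1L, 1L, 1L)))
  cm <- confusion(1, 2, 3)
  expect_identical(sum(cm), 1L)
  expect_identical(cm[1, 2], 1L)
  cm <- confusion(c(1, 1, 2, 2, 2), c(1, 2, 2, 2, 1), 2)
  expect_identical(sum(cm), 5L)
  expect_error(confusion(c(1, 2), 1), "lengths")
  expect_error(confusion(c(1, 4), c(1, 1), 3), "n_classes")
})

round_half_up_f1 <- function(pr, rc) floor(f1_score(pr, rc) * 100 + 0.5) / 100

test_that("F1 reproduces published-style worked values", {
  expect_equal(round_half_up_f1(100, 98.33), 99.16)
  expect_equal(round_half_up_f1(97.52, 100), 98.74)
})

test_that("per-class metrics agree with brute-force enumeration", {
  set.seed(8)
  mats <- c(
    lapply(1:30, function(i) matrix(rpois(9, 2), 3)),
    lapply(1:10, function(i) matrix(sample(0:3, 16, TRUE), 4))
  )
  for (cm in mats) {
    if (sum(cm) == 0) next
    rep <- suppressWarnings(per_class_metrics(cm))
    oracle <- brute_force_metrics(cm)
    expect_equal(rep$exact$accuracy, unname(oracle[, "acc"]))
    expect_equal(rep$exact$precision, unname(oracle[, "pr"]))
    expect_equal(rep$exact$recall, unname(oracle[, "rc"]))
    expect_equal(rep$exact$f1, unname(oracle[, "f1"]))
    # F1 lies between precision and recall
    ok <- !is.na(rep$exact$f1)
    expect_true(all(rep$exact$f1[ok] >=
                      pmin(rep$exact$precision, rep$exact$recall)[ok] - 1e-9))
    expect_true(all(rep$exact$f1[ok] <=
                      pmax(rep$exact$precision, rep$exact$recall)[ok] + 1e-9))
    # micro recall equals overall accuracy
    expect_equal(sum(diag(cm)) / sum(cm) * 100,
                 sum(rep$exact$recall * rep$counts, na.rm = TRUE) /
                   sum(rep$counts[!is.na(rep$exact$recall)]),
                 tolerance = 1e-9)
  }
})

test_that("zero denominators are reported as undefined, not zero", {
  cm <- matrix(c(2L, 0L, 0L, 0L), 2)  # class 2 never occurs
  expect_warning(rep <- per_class_metrics(cm), "undefined")
  expect_true(is.na(rep$per_class$precision[2]))
  expect_true(is.na(rep$per_class$recall[2]))
  expect_false(is.na(rep$per_class$accuracy[2]))
})

test_that("the mosquito-style worked example reproduces its report", {
  cm <- mosquito_confusion()
  rep <- per_class_metrics(cm)
  expect_identical(rep$per_class$n,
                   c(120, 120, 118, 108, 180, 119))
  expect_equal(rep$per_class$accuracy,
               c(100, 99.74, 99.61, 99.61, 99.87, 99.61))
  expect_equal(rep$per_class$precision,
               c(100, 100, 97.52, 100, 100, 97.54))
  expect_equal(rep$per_class$recall,
               c(100, 98.33, 100, 97.22, 99.44, 100))
  expect_equal(rep$per_class$f1,
               c(100, 99.16, 98.74, 98.59, 99.72, 98.76))
  ov <- overall_metrics(rep)
  expect_equal(ov$accuracy, 99.22)
  expect_equal(ov$precision, 99.24)
  expect_equal(ov$recall, 99.22)
  expect_equal(ov$f1, 99.22)
  # one-vs-rest accuracy derivation: two errors out of 765
  expect_equal(floor((765 - 2) / 765 * 10000 + 0.5) / 100, 99.74)
})

test_that("overall metrics degenerate sensibly", {
  cm <- matrix(c(8L, 2L, 1L, 9L), 2, byrow = TRUE)
  rep <- per_class_metrics(cm)
  # equal counts: weighted mean equals plain mean
  expect_equal(overall_metrics(rep)$f1,
               overall_metrics(rep, weighted = FALSE)$f1)
  single <- per_class_metrics(matrix(5L, 1, 1))
  ov <- overall_metrics(single)
  expect_equal(ov$accuracy, 100)
  expect_equal(ov$recall, 100)
})

test_that("evaluate scores a trained model end to end", {
  ds <- tiny_dataset(per_class = 10, noise = 0, seed = 3)
  fit <- train_classifier(build_reference_cnn(32, 6, widths = c(12, 24),
                                              seed = 11), ds,
                          kd_config(epochs = 12, learning_rate = 1e-3,
                                    seed = 3))
  res <- evaluate(fit, ds)
  expect_identical(sum(res$confusion), 12L)  # 2 validation x 6 classes
  expect_equal(res$accuracy, 1)
  expect_equal(res$overall$f1, 100)
  expect_identical(res$cost$params, count_params(fit$model$graph))
  # repeated evaluation of a fixed model is identical
  res2 <- evaluate(fit, ds)
  expect_identical(res$confusion, res2$confusion)
  unsplit <- tiny_dataset(per_class = 4, split = FALSE)
  expect_error(evaluate(fit, unsplit), "validation")
})
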