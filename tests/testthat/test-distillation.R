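# Frozen derived values:
# tempered_softmax(c(1, 0), 2) = exp(.5)/(exp(.5)+1) = 0.6224593 ...
# soft_loss(c(.5,.5), c(.25,.75)) = .5*ln2 + .5*ln(2/3) = 0.1438410 ...
# hard_loss(uniform over 6) = ln 6 = 1.7917595 ...

test_that("tempered softmax softens and reduces to softmax at tau = 1", {
  expect_equal(tempered_softmax(c(0, 0), 2), c(0.5, 0.5))
  expect_equal(tempered_softmax(c(1, 0), 2),
               c(0.6224593312, 0.3775406688), tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    lg <- rnorm(6, sd = 3)
    std <- exp(lg - max(lg)) / sum(exp(lg - max(lg)))  # reference softmax
    expect_equal(tempered_softmax(lg, 1), std, tolerance = 1e-12)
    # sums to one at any temperature
    for (tau in c(0.5, 1, 2, 10)) {
      p <- tempered_softmax(lg, tau)
      expect_lt(abs(sum(p) - 1), 1e-6)
    }
    # raising tau shrinks the max-min probability gap
    gaps <- vapply(c(1, 2, 4, 8),
                   function(tau) diff(range(tempered_softmax(lg, tau))), 0)
    expect_true(all(diff(gaps) < 0))
  }
  expect_error(tempered_softmax(c(1, 0), 0), "tau")
  # matrix form operates row-wise
  m <- rbind(c(1, 0), c(0, 0))
  pm <- tempered_softmax(m, 2)
  expect_equal(pm[1, ], tempered_softmax(c(1, 0), 2))
  expect_equal(pm[2, ], c(0.5, 0.5))
})

test_that("soft loss is KL(teacher || student)", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(soft_loss(p, p), 0)
  expect_equal(soft_loss(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    a <- tempered_softmax(rnorm(5), 1)
    b <- tempered_softmax(rnorm(5), 1)
    expect_gte(soft_loss(a, b), 0)
  }
  expect_error(soft_loss(c(0.5, 0.5), c(1, 0, 0)), "lengths")
})

test_that("hard loss is categorical cross-entropy", {
  expect_equal(hard_loss(c(0, 1, 0), 2), 0)
  expect_equal(hard_loss(rep(1 / 6, 6), 3), log(6), tolerance = 1e-12)
  # decreasing in the true-class probability
  ps <- seq(0.1, 0.9, by = 0.2)
  losses <- vapply(ps, function(p) hard_loss(c(p, 1 - p), 1), 0)
  expect_true(all(diff(losses) < 0))
  # batch form averages
  batch <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(hard_loss(batch, c(1, 2)),
               mean(-log(c(0.8, 0.6))), tolerance = 1e-12)
  expect_error(hard_loss(c(0.5, 0.5), 3), "range")
})

test_that("total loss mixes soft and hard by alpha", {
  expect_equal(total_loss(2, 1, 0.3), 1.7)
  expect_equal(total_loss(5, 9, 1), 9)
  expect_equal(total_loss(5, 9, 0), 5)
  expect_error(total_loss(1, 1, 1.5), "alpha")
  # linear in both arguments; swapping roles mirrors alpha
  s <- 1.3; h <- 0.4; a <- 0.25
  expect_equal(total_loss(2 * s, h, a),
               2 * total_loss(s, h, a) - h * a)
  expect_equal(total_loss(s, h, a), total_loss(h, s, 1 - a))
})

test_that("kd_config validates its hyper-parameters", {
  cfg <- kd_config()
  expect_equal(cfg$temperature, 2)
  expect_equal(cfg$alpha, 0.3)
  expect_equal(cfg$batch_size, 16L)
  expect_equal(cfg$epochs, 30L)
  expect_error(kd_config(temperature = 0), "temperature")
  expect_error(kd_config(alpha = -0.1), "alpha")
  expect_error(kd_config(optimizer = "sgd"), "adam")
})

test_that("plain training drives a separable set to perfect accuracy", {
  ds <- tiny_dataset(per_class = 8, noise = 0, seed = 7)
  fit <- train_classifier(build_reference_cnn(32, 6, widths = c(12, 24),
                                              seed = 11), ds,
                          kd_config(epochs = 12, learning_rate = 1e-3,
                                    seed = 7))
  expect_identical(nrow(fit$history), 12L)
  expect_equal(fit$history$accuracy[12], 1)
})

test_that("training is deterministic given a seed", {
  ds <- tiny_dataset(per_class = 4, noise = 0.1, seed = 2)
  cfg <- kd_config(epochs = 2, learning_rate = 1e-3, seed = 5)
  f1 <- train_classifier(plain_graph(seed = 3), ds, cfg)
  f2 <- train_classifier(plain_graph(seed = 3), ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("training rejects a class with no samples", {
  ds <- tiny_dataset(per_class = 4, noise = 0, seed = 1, split = FALSE)
  keep <- ds$manifest$class != "class03"
  ds$manifest <- ds$manifest[keep, ]
  ds$images <- ds$images[, , , keep, drop = FALSE]
  expect_error(train_classifier(plain_graph(), ds, kd_config(epochs = 1)),
               "no training samples")
})

test_that("distillation with alpha = 1 reduces to plain training", {
  ds <- tiny_dataset(per_class = 4, noise = 0.1, seed = 9)
  cfg <- kd_config(alpha = 1, epochs = 2, learning_rate = 1e-3, seed = 4)
  g <- plain_graph(seed = 21)
  teacher <- train_classifier(plain_graph(seed = 31), ds,
                              kd_config(epochs = 1, seed = 1))
  kd_fit <- distill(teacher, g, ds, cfg)
  plain_fit <- train_classifier(g, ds, cfg)
  expect_equal(kd_fit$history$hard_loss, plain_fit$history$loss,
               tolerance = 1e-12)
  expect_equal(kd_fit$model$params, plain_fit$model$params,
               tolerance = 1e-12)
})

test_that("an identical teacher yields ~zero soft loss at tau = 1", {
  ds <- tiny_dataset(per_class = 4, noise = 0.1, seed = 6)
  g <- plain_graph(seed = 13)  # batchnorm-free: train == eval behaviour
  teacher <- structure(list(model = init_model(g), history = NULL,
                            config = NULL), class = "cenkd_fit")
  fit <- distill(teacher, g, ds,
                 kd_config(temperature = 1, alpha = 0, learning_rate = 0,
                           epochs = 1, seed = 6))
  expect_lt(fit$history$soft_loss[1], 1e-10)
})

test_that("distillation rejects mismatched head widths", {
  ds <- tiny_dataset(per_class = 4, noise = 0, seed = 1)
  teacher <- train_classifier(plain_graph(num_classes = 6), ds,
                              kd_config(epochs = 1, seed = 1))
  bad_student <- plain_graph(num_classes = 6)
  bad_student$nodes$head_dense$units <- 4L
  expect_error(distill(teacher, bad_student, ds, kd_config(epochs = 1)))
})
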