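test_that("synthesis is deterministic and honors the spec counts", {
  sp <- synth_spec(classes = 6, per_class = 5, image_size = 32,
                   noise = 0.2, seed = 42)
  d1 <- synthesize_dataset(sp)
  d2 <- synthesize_dataset(sp)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(nrow(d1$manifest), 30L)
  expect_true(all(table(d1$manifest$class) == 5L))
  expect_true(all(d1$images >= 0 & d1$images <= 1))
  d3 <- synthesize_dataset(synth_spec(classes = 6, per_class = 5,
                                      image_size = 32, noise = 0.2,
                                      seed = 43))
  expect_false(identical(d1$images, d3$images))
})

test_that("noise-free classes are linearly separable on raw pixels", {
  ds <- synthesize_dataset(synth_spec(classes = 6, per_class = 12,
                                      image_size = 32, noise = 0, seed = 1))
  expect_equal(linear_probe(ds), 1)
})

test_that("class separability degrades as noise grows", {
  acc <- vapply(c(0, 0.4, 1.2), function(nz) {
    mean(vapply(1:2, function(seed) {
      ds <- split_dataset(synthesize_dataset(
        synth_spec(classes = 6, per_class = 15, image_size = 32,
                   noise = nz, seed = seed)), 0.8, seed = seed)
      linear_probe(ds, holdout = TRUE)
    }, 0))
  }, 0)
  expect_true(all(diff(acc) <= 0))
  expect_lt(acc[3], acc[1])
})

test_that("the 80/20 splitter reproduces published-style per-class counts", {
  man <- data.frame(
    sample = sprintf("s%04d", 1:1191),
    class = rep(c("a", "b"), times = c(600, 591)),
    split = NA_character_)
  out <- split_dataset(man, 0.8, seed = 1)
  expect_identical(sum(out$split == "train" & out$class == "a"), 480L)
  expect_identical(sum(out$split == "validation" & out$class == "a"), 120L)
  expect_identical(sum(out$split == "train" & out$class == "b"), 473L)
  expect_identical(sum(out$split == "validation" & out$class == "b"), 118L)
})

test_that("splitting partitions every class, stably and stratified", {
  set.seed(10)
  for (i in 1:5) {
    n_per <- sample(5:50, 3)
    man <- data.frame(
      sample = sprintf("s%04d", seq_len(sum(n_per))),
      class = rep(letters[1:3], times = n_per),
      split = NA_character_)
    frac <- runif(1, 0.5, 0.9)
    o1 <- split_dataset(man, frac, seed = i)
    o2 <- split_dataset(man, frac, seed = i)
    expect_identical(o1, o2)
    expect_true(all(o1$split %in% c("train", "validation")))
    for (cls in letters[1:3]) {
      sub <- o1[o1$class == cls, ]
      n_train <- sum(sub$split == "train")
      expect_identical(n_train + sum(sub$split == "validation"), nrow(sub))
      expect_lte(abs(n_train - frac * nrow(sub)), 1)
    }
  }
  expect_error(split_dataset(man, 1.2), "train_fraction")
  tiny <- data.frame(sample = "x", class = "a", split = NA_character_)
  expect_error(split_dataset(tiny, 0.8), "fewer than 2")
})

test_that("manifest summary reproduces the six-class mosquito tally", {
  counts <- data.frame(
    class = c("Non-Vector", "Aedes albopictus", "Aedes vexans",
              "Anopheles sinensis", "Culex pipiens",
              "Culex tritaeniorhynchus"),
    train = c(480L, 480L, 473L, 485L, 420L, 475L),
    validation = c(120L, 120L, 118L, 108L, 180L, 119L))
  man <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(
      sample = sprintf("%s_%04d", counts$class[i],
                       seq_len(counts$train[i] + counts$validation[i])),
      class = counts$class[i],
      split = rep(c("train", "validation"),
                  c(counts$train[i], counts$validation[i])))
  }))
  sm <- manifest_summary(man)
  total <- sm[sm$class == "Total", ]
  expect_identical(total$train, 2813L)
  expect_identical(total$validation, 765L)
  expect_identical(total$total, 3578L)
  expect_identical(sm$total[match("Anopheles sinensis", sm$class)], 593L)
  # unsplit manifests report totals only
  man$split <- NA_character_
  sm2 <- manifest_summary(man)
  expect_true(all(is.na(sm2$train)))
  expect_identical(sm2$total[sm2$class == "Total"], 3578L)
})

test_that("datasets survive a write/load round trip", {
  ds <- split_dataset(synthesize_dataset(
    synth_spec(classes = 3, per_class = 4, image_size = 16, noise = 0.1,
               seed = 5)), 0.75, seed = 5)
  dir <- tempfile("imgds")
  write_dataset(ds, dir)
  back <- load_image_folder(dir)
  expect_identical(back$classes, ds$classes)
  expect_identical(nrow(back$manifest), nrow(ds$manifest))
  expect_identical(manifest_summary(back), manifest_summary(ds))
  # PNG quantizes to 8 bits
  ord <- match(file.path(ds$manifest$class, basename(ds$manifest$sample)),
               back$manifest$sample)
  expect_lte(max(abs(back$images[, , , ord] - ds$images)), 1 / 255)
  unlink(dir, recursive = TRUE)
})

test_that("unreadable files are skipped with a warning; empty dirs error", {
  ds <- synthesize_dataset(synth_spec(classes = 2, per_class = 2,
                                      image_size = 16, noise = 0, seed = 1))
  dir <- tempfile("imgds")
  write_dataset(ds, dir)
  writeLines("not an image", file.path(dir, "class01", "junk.png"))
  expect_warning(back <- load_image_folder(dir), "skipped 1")
  expect_identical(nrow(back$manifest), 4L)
  unlink(dir, recursive = TRUE)
  expect_error(load_image_folder(tempfile()), "does not exist")
  empty <- tempfile(); dir.create(empty)
  expect_error(load_image_folder(empty), "class folders")
})
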