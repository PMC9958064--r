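# Dataset handling: a procedural 6-class synthetic image generator (so
# every other module is testable without downloads), the stratified
# 80/20 splitter, image-folder ingestion and manifest summaries.

#' Specification of a synthetic image dataset
#'
#' Each class is a distinct parametric family: an oriented sinusoidal
#' grating at a class-specific frequency and angle (with random phase
#' and amplitude jitter per sample) superimposed on a class-specific
#' fixed blob layout and a class-specific RGB tint, plus additive
#' Gaussian pixel noise. The fixed blob/tint component gives every class
#' a distinct mean image, so at `noise = 0` the classes are separable by
#' a linear probe on raw pixels; raising `noise` degrades separability
#' smoothly.
#'
#' @param classes number of classes (default 6).
#' @param per_class samples per class.
#' @param image_size square image side in pixels.
#' @param noise standard deviation of the additive Gaussian pixel noise
#'   (pixels live in `[0, 1]`; images are clipped after noise).
#' @param seed RNG seed: the same spec always produces byte-identical
#'   images.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(classes = 6L, per_class = 100L, image_size = 64L,
                       noise = 0.3, seed = 1L) {
  if (classes < 2) stop("at least 2 classes are required")
  if (per_class < 1) stop("per_class must be >= 1")
  if (noise < 0) stop("noise must be >= 0")
  structure(list(classes = as.integer(classes),
                 per_class = as.integer(per_class),
                 image_size = as.integer(image_size),
                 noise = noise, seed = as.integer(seed)),
            class = "synth_spec")
}

# Deterministic hash-based pseudo-uniform in [0, 1): class geometry must
# not depend on the RNG stream so that layouts are stable across seeds.
hash_unif <- function(a, b) {
  x <- sin(a * 12.9898 + b * 78.233) * 43758.5453
  x - floor(x)
}

# Fixed per-class structure: grating frequency/angle, blob layout, tint.
class_template <- function(cls, size) {
  freq <- 3 + 2 * ((cls - 1) %% 3)
  angle <- (cls - 1) * pi / 6
  xs <- matrix(rep(seq(0, 1, length.out = size), size), size)
  ys <- t(xs)
  u <- xs * cos(angle) + ys * sin(angle)
  blobs <- matrix(0, size, size)
  for (j in 1:3) {
    cx <- 0.15 + 0.7 * hash_unif(cls, j)
    cy <- 0.15 + 0.7 * hash_unif(cls + 17, j)
    blobs <- blobs + exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * 0.08^2))
  }
  tint <- 0.1 * c(hash_unif(cls, 101), hash_unif(cls, 202),
                  hash_unif(cls, 303))
  list(u = u, freq = freq, blobs = blobs, tint = tint)
}

#' Generate a synthetic labeled image dataset
#'
#' Draws `per_class` images for each of the `classes` procedural classes
#' described by [synth_spec()]. Deterministic given the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return an `image_dataset`: list with `images` (`H x W x 3 x N`
#'   array, pixels in `[0, 1]`), `manifest` (data frame with `sample`,
#'   `class`, `split` columns; split initially unassigned), `classes`,
#'   `image_size` and `seed`.
#' @export
synthesize_dataset <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  size <- spec$image_size
  n <- spec$classes * spec$per_class
  classes <- sprintf("class%02d", seq_len(spec$classes))
  images <- array(0, dim = c(size, size, 3L, n))
  sample_id <- character(n)
  sample_class <- character(n)
  i <- 0L
  for (cls in seq_len(spec$classes)) {
    tpl <- class_template(cls, size)
    for (j in seq_len(spec$per_class)) {
      i <- i + 1L
      phase <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0.8, 1.2)
      grating <- sin(2 * pi * tpl$freq * tpl$u + phase)
      base <- 0.35 + 0.4 * tpl$blobs + 0.2 * amp * grating
      for (ch in 1:3) {
        px <- base + tpl$tint[ch]
        if (spec$noise > 0) px <- px + rnorm(size * size, sd = spec$noise)
        images[, , ch, i] <- pmin(pmax(px, 0), 1)
      }
      sample_id[i] <- sprintf("%s_img%04d.png", classes[cls], j)
      sample_class[i] <- classes[cls]
    }
  }
  manifest <- data.frame(sample = sample_id, class = sample_class,
                         split = NA_character_, stringsAsFactors = FALSE)
  structure(list(images = images, manifest = manifest, classes = classes,
                 image_size = size, noise = spec$noise, seed = spec$seed),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat("<image_dataset> ", nrow(x$manifest), " samples, ",
      length(x$classes), " classes, ", x$image_size, "x", x$image_size,
      " px\n", sep = "")
  invisible(x)
}

#' Stratified train/validation split
#'
#' Splits every class independently: the train count is
#' `round(train_fraction * class_total)` (half-up) and the remainder goes
#' to validation, after a seeded shuffle. The default 80/20 follows the
#' Pareto-principle split convention.
#'
#' @param manifest an `image_dataset` or a manifest data frame with
#'   `sample`, `class`, `split` columns.
#' @param train_fraction fraction assigned to training (strictly between
#'   0 and 1).
#' @param seed shuffle seed; the same manifest and seed always give the
#'   same assignment.
#' @return the input with its `split` column filled with
#'   `"train"`/`"validation"`.
#' @export
split_dataset <- function(manifest, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  ds <- NULL
  if (inherits(manifest, "image_dataset")) {
    ds <- manifest
    manifest <- ds$manifest
  }
  set.seed(seed)
  split <- rep(NA_character_, nrow(manifest))
  for (cls in unique(manifest$class)) {
    idx <- which(manifest$class == cls)
    if (length(idx) < 2) {
      stop("class '", cls, "' has fewer than 2 samples; cannot split")
    }
    n_train <- floor(train_fraction * length(idx) + 0.5)
    shuffled <- sample(idx)
    split[shuffled[seq_len(n_train)]] <- "train"
    split[shuffled[-seq_len(n_train)]] <- "validation"
  }
  manifest$split <- split
  if (!is.null(ds)) {
    ds$manifest <- manifest
    return(ds)
  }
  manifest
}

#' Summarize a dataset manifest
#'
#' Per-class train/validation/total counts plus a grand-total row, in
#' the layout of a dataset specification table. When no split tags are
#' assigned only totals are reported.
#'
#' @param manifest an `image_dataset` or manifest data frame.
#' @return a data frame with columns `class`, `train`, `validation`,
#'   `total`; the final row is the grand total.
#' @export
manifest_summary <- function(manifest) {
  if (inherits(manifest, "image_dataset")) manifest <- manifest$manifest
  classes <- unique(manifest$class)
  has_split <- !all(is.na(manifest$split))
  rows <- lapply(classes, function(cls) {
    sub <- manifest[manifest$class == cls, ]
    data.frame(class = cls,
               train = if (has_split) sum(sub$split == "train", na.rm = TRUE)
                       else NA_integer_,
               validation = if (has_split)
                 sum(sub$split == "validation", na.rm = TRUE)
                 else NA_integer_,
               total = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total_row <- data.frame(class = "Total",
                          train = if (has_split) sum(out$train) else NA_integer_,
                          validation = if (has_split) sum(out$validation)
                                       else NA_integer_,
                          total = sum(out$total), stringsAsFactors = FALSE)
  rbind(out, total_row)
}

#' Write an image dataset to a class-per-folder directory
#'
#' One subdirectory per class, PNG images, plus a `manifest.csv`
#' (sample path, class, split) at the top level.
#'
#' @param dataset an `image_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "image_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  for (cls in dataset$classes) {
    dir.create(file.path(dir, cls), showWarnings = FALSE)
  }
  for (i in seq_len(nrow(man))) {
    png::writePNG(dataset$images[, , , i],
                  file.path(dir, man$class[i], basename(man$sample[i])))
  }
  out <- man
  out$sample <- file.path(out$class, basename(out$sample))
  write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load an image-folder dataset
#'
#' Expects one subdirectory per class containing PNG images (classes are
#' ordered lexicographically). Files that cannot be read as PNG are
#' skipped with a warning reporting their count. All images must share
#' one square size; grayscale images are expanded to three channels.
#'
#' @param path dataset directory.
#' @return an `image_dataset` (split unassigned, or recovered from a
#'   `manifest.csv` written by [write_dataset()] if present).
#' @export
load_image_folder <- function(path) {
  if (!dir.exists(path)) stop("directory '", path, "' does not exist")
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("'", path, "' contains no class folders")
  files <- list()
  labs <- character()
  for (cls in classes) {
    fl <- sort(list.files(file.path(path, cls), full.names = TRUE))
    files <- c(files, as.list(fl))
    labs <- c(labs, rep(cls, length(fl)))
  }
  if (length(files) == 0) stop("'", path, "' contains no images")
  imgs <- vector("list", length(files))
  keep <- logical(length(files))
  for (i in seq_along(files)) {
    img <- tryCatch(png::readPNG(files[[i]]), error = function(e) NULL)
    if (is.null(img)) next
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    imgs[[i]] <- img
    keep[i] <- TRUE
  }
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    warning("skipped ", n_skipped, " unreadable file(s) in '", path, "'")
  }
  if (!any(keep)) stop("'", path, "' contains no readable PNG images")
  imgs <- imgs[keep]
  labs <- labs[keep]
  paths <- unlist(files)[keep]
  sizes <- vapply(imgs, function(im) dim(im)[1], 0L)
  if (length(unique(sizes)) != 1) {
    stop("images have mixed sizes; a uniform square size is required")
  }
  size <- sizes[1]
  images <- array(0, dim = c(size, size, 3L, length(imgs)))
  for (i in seq_along(imgs)) images[, , , i] <- imgs[[i]]
  manifest <- data.frame(sample = file.path(labs, basename(paths)),
                         class = labs, split = NA_character_,
                         stringsAsFactors = FALSE)
  man_csv <- file.path(path, "manifest.csv")
  if (file.exists(man_csv)) {
    stored <- read.csv(man_csv, stringsAsFactors = FALSE)
    m <- match(manifest$sample, stored$sample)
    if (!anyNA(m) && "split" %in% names(stored)) {
      manifest$split <- stored$split[m]
    }
  }
  structure(list(images = images, manifest = manifest, classes = classes,
                 image_size = size, noise = NA_real_, seed = NA_integer_),
            class = "image_dataset")
}

#' Linear-probe training accuracy on raw pixels
#'
#' Fits a one-vs-rest ridge regression (dual form) from raw pixels to
#' one-hot labels and reports argmax training accuracy. Used as an
#' independent yardstick of class separability: at zero noise the
#' synthetic classes are linearly separable (accuracy 1), and separation
#' degrades as noise grows.
#'
#' @param dataset an `image_dataset`.
#' @param lambda ridge penalty (relative to the mean kernel diagonal).
#' @param holdout fit on the training split and score the validation
#'   split (requires split tags) instead of reporting training accuracy.
#' @return accuracy in `[0, 1]`.
#' @export
linear_probe <- function(dataset, lambda = 1e-6, holdout = FALSE) {
  stopifnot(inherits(dataset, "image_dataset"))
  n <- nrow(dataset$manifest)
  X <- t(matrix(dataset$images, ncol = n))  # n x pixels
  X <- sweep(X, 2, colMeans(X))
  y <- match(dataset$manifest$class, dataset$classes)
  tr <- if (holdout) {
    if (all(is.na(dataset$manifest$split))) {
      stop("holdout probe requires an assigned split")
    }
    which(dataset$manifest$split == "train")
  } else {
    seq_len(n)
  }
  te <- if (holdout) which(dataset$manifest$split == "validation") else tr
  Y <- matrix(0, length(tr), length(dataset$classes))
  Y[cbind(seq_along(tr), y[tr])] <- 1
  K <- tcrossprod(X[tr, , drop = FALSE])
  lam <- lambda * mean(diag(K))
  alpha <- solve(K + diag(lam, length(tr)), Y)
  scores <- X[te, , drop = FALSE] %*% t(X[tr, , drop = FALSE]) %*% alpha
  mean(max.col(scores) == y[te])
}
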