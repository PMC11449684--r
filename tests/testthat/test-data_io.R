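test_that("phantom generation is deterministic, balanced and in range", {
  ph <- generate_phantoms(n_per_class = 5, image_size = c(64, 64),
                          noise_sd = 0, seed = 7)
  expect_equal(length(ph), 20)
  expect_equal(as.vector(table(ph$labels)), rep(5, 4))
  expect_equal(ph$class_names,
               c("glioma", "meningioma", "notumor", "pituitary"))
  expect_true(all(ph$images >= 0 & ph$images <= 1))
  ph2 <- generate_phantoms(n_per_class = 5, image_size = c(64, 64),
                           noise_sd = 0, seed = 7)
  expect_identical(ph$images, ph2$images)
  ph3 <- generate_phantoms(n_per_class = 5, image_size = c(64, 64),
                           noise_sd = 0, seed = 8)
  expect_false(identical(ph$images, ph3$images))
  expect_error(generate_phantoms(noise_sd = 0.7), "noise_sd")
})

test_that("phantom class-conditional means are pairwise separated", {
  ph <- tiny_phantoms()
  noise_sd <- 0.05
  means <- lapply(1:4, function(k)
    apply(ph$images[, , 1, ph$labels == k], c(1, 2), mean))
  for (a in 1:3) for (b in (a + 1):4) {
    d <- sqrt(sum((means[[a]] - means[[b]])^2))
    expect_gt(d, 5 * noise_sd)
  }
})

test_that("a nearest-centroid baseline separates downsampled phantoms", {
  # independent of the CNN: class centroids of 8x8 block-mean thumbnails
  ph <- generate_phantoms(n_per_class = 100, image_size = c(64, 64),
                          noise_sd = 0.05, seed = 31)
  block_mean <- function(img, g = 8) {
    b <- nrow(img) / g
    m <- rowsum(img, rep(seq_len(g), each = b))          # pool rows
    t(rowsum(t(m), rep(seq_len(g), each = b))) / b^2     # pool columns
  }
  thumb <- function(i) as.vector(block_mean(ph$images[, , 1, i]))
  X <- t(vapply(seq_len(length(ph)), thumb, numeric(64)))
  train <- unlist(lapply(1:4, function(k) which(ph$labels == k)[1:50]))
  test <- setdiff(seq_len(length(ph)), train)
  cent <- t(vapply(1:4, function(k)
    colMeans(X[intersect(train, which(ph$labels == k)), ]), numeric(64)))
  pred <- apply(X[test, ], 1, function(v)
    which.min(colSums((t(cent) - v)^2)))
  expect_gt(mean(pred == ph$labels[test]), 0.9)
})

test_that("stratified splitting is a seeded partition with exact proportions", {
  ph <- generate_phantoms(n_per_class = 25, image_size = c(32, 32),
                          noise_sd = 0.02, seed = 5)
  sp <- split_dataset(ph, c(0.7, 0.1, 0.2), seed = 3)
  idx <- attr(sp, "indices")
  all_idx <- sort(unname(unlist(idx)))
  expect_identical(all_idx, 1:100)                 # partition, no repeats
  expect_equal(length(sp$train), 70)
  expect_equal(length(sp$val), 10)
  expect_equal(length(sp$test), 20)
  for (k in 1:4) {
    expect_true(sum(sp$train$labels == k) %in% 17:18)
    expect_true(sum(sp$val$labels == k) %in% 2:3)
    expect_equal(sum(sp$test$labels == k), 5)
  }
  sp2 <- split_dataset(ph, c(0.7, 0.1, 0.2), seed = 3)
  expect_identical(attr(sp2, "indices"), idx)      # seed reproducibility
  sp3 <- split_dataset(ph, c(0.7, 0.1, 0.2), seed = 4)
  expect_false(identical(attr(sp3, "indices"), idx))
  expect_error(split_dataset(ph, c(0.5, 0.5, 0.1)), "sum to 1")
  expect_error(split_dataset(ph, c(0.7, 0.1, 0.2, 0.0)), "3 values")
})

test_that("splitting fails loudly when a class is too small", {
  imgs <- array(runif(4 * 4 * 3 * 5), dim = c(4, 4, 3, 5))
  set <- labeled_image_set(imgs, c(1, 1, 1, 2, 2), c("a", "b"))
  expect_error(split_dataset(set, c(0.7, 0.1, 0.2), seed = 1), "'b'")
})

test_that("folder round trip preserves classes, shape and scale", {
  ph <- generate_phantoms(n_per_class = 3, image_size = c(48, 48),
                          noise_sd = 0.02, seed = 9)
  d <- file.path(tempdir(), "phantom_tree")
  unlink(d, recursive = TRUE)
  write_image_folder(ph, d)
  reread <- load_image_folder(d, target_size = c(48, 48))
  expect_equal(length(reread), 12)
  expect_equal(reread$class_names, ph$class_names)  # alphabetical order
  expect_equal(dim(reread$images)[1:3], c(48, 48, 3))
  expect_true(all(reread$images >= 0 & reread$images <= 1))
  # 8-bit quantization is the only loss
  expect_lt(max(abs(reread$images - ph$images)), 1 / 255)
  # resizing on reload changes shape but stays in range
  small <- load_image_folder(d, target_size = c(24, 24))
  expect_equal(dim(small$images)[1:3], c(24, 24, 3))
  unlink(d, recursive = TRUE)
})

test_that("undecodable files are skipped and empty classes are an error", {
  ph <- generate_phantoms(n_per_class = 2, image_size = c(24, 24),
                          noise_sd = 0, seed = 2)
  d <- file.path(tempdir(), "phantom_bad")
  unlink(d, recursive = TRUE)
  write_image_folder(ph, d)
  writeLines("not an image", file.path(d, "glioma", "broken.png"))
  expect_warning(set <- load_image_folder(d, target_size = c(24, 24)),
                 "skipping")
  expect_equal(attr(set, "n_skipped"), 1L)
  expect_equal(length(set), 8)
  # remove every image from one class
  unlink(list.files(file.path(d, "pituitary"), full.names = TRUE))
  expect_error(suppressWarnings(load_image_folder(d, target_size = c(24, 24))),
               "pituitary")
  unlink(d, recursive = TRUE)
})

test_that("images load to 3 channels from grayscale sources", {
  d <- file.path(tempdir(), "gray_tree", "classA")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  g <- matrix(runif(16 * 16), 16, 16)
  EBImage::writeImage(EBImage::Image(g), file.path(d, "g.png"))
  expect_warning(set <- load_image_folder(dirname(d), target_size = c(16, 16)),
                 "class folder")
  expect_equal(dim(set$images), c(16, 16, 3, 1))
  expect_equal(set$images[, , 1, 1], set$images[, , 2, 1])
  unlink(dirname(d), recursive = TRUE)
})

test_that("a missing class folder loads with K = 3 and a warning", {
  ph <- generate_phantoms(n_per_class = 2, image_size = c(24, 24),
                          noise_sd = 0, seed = 4)
  d <- file.path(tempdir(), "phantom_k3")
  unlink(d, recursive = TRUE)
  write_image_folder(ph, d)
  unlink(file.path(d, "notumor"), recursive = TRUE)
  expect_warning(set <- load_image_folder(d, target_size = c(24, 24)),
                 "4")
  expect_length(set$class_names, 3)
  expect_equal(length(set), 6)
  unlink(d, recursive = TRUE)
})
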