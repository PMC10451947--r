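# Synthetic vein generator, ROI preprocessing and dataset splitting.

small_cfg <- function(seed = 1, n_id = 6, per_id = 6) {
  synthetic_vein_config(n_identities = n_id, images_per_identity = per_id,
                        n_sessions = 2, roi_size = c(50, 150), seed = seed)
}

test_that("the generator emits the configured number of labelled images", {
  ds <- generate_synthetic_dataset(small_cfg())
  expect_length(ds$images, 36)
  expect_equal(as.vector(table(ds$labels)), rep(6, 6))
  expect_equal(sort(unique(ds$sessions)), c(1L, 2L))
  expect_true(all(vapply(ds$images, function(im)
    all(im >= 0 & im <= 1), logical(1))))
  expect_equal(dim(ds$images[[1]]), c(50L, 150L))
})

test_that("generation is a pure function of the seed", {
  a <- generate_synthetic_dataset(small_cfg(seed = 5))
  b <- generate_synthetic_dataset(small_cfg(seed = 5))
  expect_identical(a$images, b$images)
  c2 <- generate_synthetic_dataset(small_cfg(seed = 6))
  expect_false(identical(a$images, c2$images))
})

test_that("within-identity images are more similar than between-identity", {
  ds <- generate_synthetic_dataset(
    synthetic_vein_config(n_identities = 12, images_per_identity = 4,
                          n_sessions = 2, roi_size = c(50, 150), seed = 3))
  v <- vapply(ds$images, as.vector, numeric(50 * 150))
  cm <- cor(v)
  same <- outer(ds$labels, ds$labels, "==") & upper.tri(cm)
  diff <- outer(ds$labels, ds$labels, "!=") & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[diff]))
})

test_that("a nearest-mean pixel classifier clears the chance floor", {
  ds <- generate_synthetic_dataset(small_cfg(seed = 9, n_id = 8))
  sp <- split_dataset(ds$labels, split_spec(c(4, 1, 1), seed = 9))
  v <- vapply(ds$images, as.vector, numeric(50 * 150))
  centroids <- sapply(1:8, function(cl)
    rowMeans(v[, sp$train[ds$labels[sp$train] == cl], drop = FALSE]))
  pred <- apply(v[, sp$test], 2, function(z)
    which.max(cor(z, centroids)))
  acc <- mean(pred == ds$labels[sp$test])
  expect_gt(acc, 3 / 8)  # chance = 1/8
})

test_that("preprocess_roi pads to square, resizes and replicates channels", {
  set.seed(51)
  img <- matrix(runif(100 * 300), 100, 300)
  out <- preprocess_roi(img)
  expect_equal(dim(out), c(112L, 112L, 3L, 1L))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out[, , 1, ], out[, , 2, ])
  # the 100 data rows sit centred between zero bands after padding to
  # 300 x 300: the top/bottom ~third of the resized image is black
  expect_true(all(out[1:35, , 1, 1] == 0))
  expect_true(all(out[78:112, , 1, 1] == 0))
  expect_gt(mean(out[45:68, , 1, 1]), 0.2)

  sq <- matrix(runif(112 * 112), 112, 112)
  out2 <- preprocess_roi(sq)
  expect_equal(out2[, , 1, 1], sq)  # already square at target: no-op

  expect_true(all(preprocess_roi(matrix(0, 60, 80)) == 0))
})

test_that("split_dataset divides each class proportionally and exactly", {
  labels <- rep(1:5, each = 12)
  sp <- split_dataset(labels, split_spec(c(4, 1, 1), seed = 2))
  for (cl in 1:5) {
    expect_length(intersect(sp$train, which(labels == cl)), 8)
    expect_length(intersect(sp$val, which(labels == cl)), 2)
    expect_length(intersect(sp$test, which(labels == cl)), 2)
  }
  expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_along(labels))

  labels5 <- rep(1:4, each = 5)
  sp5 <- split_dataset(labels5, split_spec(c(3, 1, 1), seed = 2))
  expect_length(sp5$train, 12); expect_length(sp5$val, 4)
  expect_length(sp5$test, 4)

  expect_error(split_dataset(rep(1:2, c(12, 3)), split_spec(c(4, 1, 1))),
               "class 2")
})

test_that("datasets round-trip through the PNG folder layout", {
  ds <- generate_synthetic_dataset(small_cfg(seed = 4, n_id = 2, per_id = 2))
  dir <- tempfile("veins")
  write_vein_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_vein_dataset(dir)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$sessions, ds$sessions)
  # PNG quantizes to 8 bits; images agree to that precision
  for (i in seq_along(ds$images))
    expect_lt(max(abs(back$images[[i]] - ds$images[[i]])), 2 / 255)
  unlink(dir, recursive = TRUE)
})
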