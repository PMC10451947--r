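# Whole-network architecture: shape contract, fusion, profiling.

test_that("the network follows the stated shape contract", {
  set.seed(41)
  model <- build_ilcnn(ilcnn_config(10))
  x <- array(runif(112 * 112 * 3 * 2), c(112, 112, 3, 2))
  out <- ilcnn_forward(model, x)
  expect_equal(model$trace$input_flow_dim, c(56L, 56L, 16L))
  expect_equal(model$trace$middle_flow_dim, c(4L, 4L, 256L))
  expect_equal(model$trace$pooled_len, 256L)
  expect_equal(dim(out$embedding), c(256L, 2L))
  expect_equal(dim(out$logits), c(10L, 2L))
  expect_equal(colSums(out$prob), c(1, 1), tolerance = 1e-12)
  expect_equal(colSums(out$embedding^2), c(1, 1), tolerance = 1e-10)
  expect_error(ilcnn_forward(model, array(0, c(64, 64, 3, 1))), "expected")
})

test_that("identical inputs give identical outputs in evaluation mode", {
  set.seed(42)
  model <- build_ilcnn(ilcnn_config(5))
  x1 <- array(runif(112 * 112 * 3), c(112, 112, 3, 1))
  x <- array(c(x1, x1), c(112, 112, 3, 2))
  out <- ilcnn_forward(model, x)
  # agreement up to BLAS blocking rounding (row position inside the batched
  # GEMM can change summation order at the 1e-17 level)
  expect_equal(out$embedding[, 1], out$embedding[, 2], tolerance = 1e-12)
  # and a repeated forward of the same batch is bitwise reproducible
  out2 <- ilcnn_forward(model, x)
  expect_identical(out$embedding, out2$embedding)
})

test_that("whole-model reparameterization preserves the forward pass", {
  for (seed in 1:3) {
    set.seed(seed)
    model <- build_ilcnn(ilcnn_config(8))
    # populate running statistics with two training batches
    invisible(ilcnn_forward(model,
      array(runif(112 * 112 * 3 * 2), c(112, 112, 3, 2)), training = TRUE))
    dep <- reparameterize_model(model)
    x <- array(runif(112 * 112 * 3 * 2), c(112, 112, 3, 2))
    a <- ilcnn_forward(model, x)
    b <- ilcnn_forward(dep, x)
    expect_lt(max(abs(a$logits - b$logits)), 1e-3)
    expect_lt(max(abs(a$logits - b$logits)), 1e-8)  # double precision margin
    expect_lt(count_parameters(dep), count_parameters(model))
    expect_error(reparameterize_model(dep), "already fused")
  }
})

test_that("profiling follows the stated conventions", {
  set.seed(43)
  model <- build_ilcnn(ilcnn_config(492))
  expect_error(profile_model(model), "fuse")
  dep <- reparameterize_model(model)
  pr <- profile_model(dep)
  # the profile must agree with a direct count of the deployed parameters
  expect_equal(pr$param_count, count_parameters(dep, include_head = FALSE))
  expect_equal(pr$param_count_with_head,
               count_parameters(dep, include_head = TRUE))
  # a single same-padded 3x3 conv 3 -> 16 at 112x112: closed-form cost
  expect_equal(3 * 3 * 3 * 16 + 16, 448)
  expect_equal(pr$mac_count %% 1, 0)
  expect_gt(pr$mac_count, 9 * 3 * 16 * 112 * 112)  # at least the input conv
})

test_that("the basic-residual ablation variant is smaller and runs", {
  set.seed(44)
  basic <- build_ilcnn(ilcnn_config(6, block = "basic", head = "linear"))
  full <- build_ilcnn(ilcnn_config(6))
  expect_lt(count_parameters(basic), count_parameters(full))
  x <- array(runif(112 * 112 * 3), c(112, 112, 3, 1))
  out <- ilcnn_forward(basic, x)
  expect_equal(dim(out$logits), c(6L, 1L))
  expect_equal(basic$trace$middle_flow_dim[3], 256L)
})

test_that("max-pool downsampling handles odd spatial extents", {
  set.seed(46)
  m <- ilcnn:::ly_maxpool2()
  x <- array(rnorm(7 * 7 * 3 * 2), c(7, 7, 3, 2))
  y <- ilcnn:::fwd(m, x, training = TRUE)
  expect_equal(dim(y), c(4L, 4L, 3L, 2L))
  # backward gradient must come back at the unpadded input size
  gx <- ilcnn:::bwd(m, array(rnorm(length(y)), dim(y)))
  expect_equal(dim(gx), dim(x))
})

test_that("checkpoints round-trip through save and load", {
  set.seed(45)
  model <- build_ilcnn(ilcnn_config(4))
  invisible(ilcnn_forward(model,
    array(runif(112 * 112 * 3), c(112, 112, 3, 1)), training = TRUE))
  x <- array(runif(112 * 112 * 3), c(112, 112, 3, 1))
  ref <- ilcnn_forward(model, x)
  path <- tempfile(fileext = ".rds")
  save_ilcnn(model, path)
  back <- load_ilcnn(path)
  expect_identical(ilcnn_forward(back, x)$logits, ref$logits)
  # fused models round-trip too
  dep <- reparameterize_model(model)
  save_ilcnn(dep, path)
  dep2 <- load_ilcnn(path)
  expect_identical(ilcnn_forward(dep2, x)$logits,
                   ilcnn_forward(dep, x)$logits)
  unlink(path)
})
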