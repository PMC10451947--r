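# Structural reparameterization: conv+BN folding, parallel and sequential
# branch merging, and full diverse-branch-block fusion.

test_that("fuse_conv_bn folds batch norm exactly", {
  set.seed(1)
  # identity BN leaves the kernel unchanged
  k <- random_kernel(3, 2, 2)
  f <- fuse_conv_bn(k, identity_bn(2))
  expect_equal(f$weights, k$weights, tolerance = 1e-12)
  expect_equal(f$bias, k$bias, tolerance = 1e-12)

  # zero kernel: fused bias is the BN shift minus scaled mean
  bn <- random_bn(3)
  kz <- fused_kernel(array(0, c(3, 3, 2, 3)), rep(0, 3))
  fz <- fuse_conv_bn(kz, bn)
  expect_equal(fz$bias,
               bn$beta - bn$mean * bn$gamma / sqrt(bn$var + bn$eps))
  expect_true(all(fz$weights == 0))

  # random kernel: fused forward == sequential conv -> BN forward
  k <- random_kernel(3, 2, 2)
  bn <- random_bn(2)
  f <- fuse_conv_bn(k, bn)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  expect_lt(max(abs(conv2d(x, f$weights, f$bias, pad = 1) -
                    ref_bn(ref_conv2d(x, k$weights, k$bias, pad = 1), bn))),
            1e-6)

  expect_error(fuse_conv_bn(k, random_bn(5)), "channel")
  expect_error(bn_stats(1, 0, 0, -1), "variance")
  expect_error(bn_stats(1, 0, 0, 1, eps = 0), "eps")
})

test_that("merge_parallel_branches sums zero-padded branch kernels", {
  set.seed(2)
  k <- random_kernel(3, 2, 3)
  doubled <- merge_parallel_branches(list(k, k), 3)
  expect_equal(doubled$weights, 2 * k$weights)
  expect_equal(doubled$bias, 2 * k$bias)

  zero <- fused_kernel(array(0, c(3, 3, 2, 3)))
  same <- merge_parallel_branches(list(k, zero), 3)
  expect_equal(same$weights, k$weights)

  # 3x3 + 1x1 branches: merged forward equals the sum of branch forwards
  k1 <- random_kernel(1, 2, 3)
  m <- merge_parallel_branches(list(k, k1), 3)
  x <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  branch_sum <- ref_conv2d(x, k$weights, k$bias, pad = 1) +
    ref_conv2d(x, k1$weights, k1$bias, pad = 0)
  expect_lt(max(abs(conv2d(x, m$weights, m$bias, pad = 1) - branch_sum)), 1e-6)

  expect_error(merge_parallel_branches(list(random_kernel(5, 2, 3)), 3),
               "odd and <=")
})

test_that("merge_sequential_1x1_kxk collapses a pointwise-then-KxK chain", {
  set.seed(3)
  # channel-identity 1x1 stage: result equals the KxK kernel
  id1 <- fused_kernel(array(diag(4), c(1, 1, 4, 4)))
  k2 <- random_kernel(3, 4, 3)
  m <- merge_sequential_1x1_kxk(id1, k2)
  expect_equal(m$weights, k2$weights, tolerance = 1e-12)
  expect_equal(m$bias, k2$bias, tolerance = 1e-12)

  # all-zero 1x1 weights: zero merged weights, bias = k2 applied to the
  # constant map of k1's bias
  b1 <- rnorm(4)
  z1 <- fused_kernel(array(0, c(1, 1, 2, 4)), b1)
  mz <- merge_sequential_1x1_kxk(z1, k2)
  expect_true(all(mz$weights == 0))
  tap <- vapply(seq_len(3), function(co) sum(k2$weights[, , , co] *
                rep(b1, each = 9)), numeric(1))
  expect_equal(mz$bias, k2$bias + tap)

  # random chain: merged forward equals the literal sequential forward with
  # the intermediate map padded by the 1x1 bias
  k1 <- random_kernel(1, 2, 4)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  z <- ref_conv2d(x, k1$weights, k1$bias, pad = 0)
  zp <- array(0, c(10, 10, 4, 1))
  for (c in 1:4) zp[, , c, ] <- k1$bias[c]
  zp[2:9, 2:9, , ] <- z
  seq_fwd <- ref_conv2d(zp, k2$weights, k2$bias, pad = 0)
  m <- merge_sequential_1x1_kxk(k1, k2)
  expect_lt(max(abs(conv2d(x, m$weights, m$bias, pad = 1) - seq_fwd)), 1e-6)

  expect_error(merge_sequential_1x1_kxk(random_kernel(1, 2, 3), k2),
               "chain mismatch")
})

test_that("avgpool_as_conv reproduces average pooling", {
  expect_equal(avgpool_as_conv(1, 3)$weights, array(diag(3), c(1, 1, 3, 3)))
  k3 <- avgpool_as_conv(3, 4)
  for (c in 1:4) expect_true(all(k3$weights[, , c, c] == 1 / 9))
  expect_equal(sum(k3$weights != 0), 4 * 9)
  expect_equal(k3$bias, rep(0, 4))

  set.seed(4)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
  got <- conv2d(x, k3$weights, k3$bias, pad = 1)
  # direct 3x3 mean with zero padding
  xp <- array(0, c(8, 8, 4, 1)); xp[2:7, 2:7, , ] <- x
  for (c in 1:4) for (i in 1:6) for (j in 1:6)
    expect_lt(abs(got[i, j, c, 1] - mean(xp[i:(i + 2), j:(j + 2), c, 1])), 1e-7)
})

test_that("reparameterize_dbb fuses the four-branch block exactly", {
  set.seed(5)
  # all BNs identity + only the KxK branch nonzero -> exactly that kernel
  dbb <- ilcnn:::ly_dbb(3, 4, 3)
  for (nm in c("bn_kxk", "bn_1x1", "bn_seq1", "bn_seq2", "bn_avg1", "bn_avg2"))
    make_bn_identity(dbb[[nm]])
  dbb$w_1x1[] <- 0; dbb$w_seq1[] <- 0; dbb$w_avg1[] <- 0
  fk <- reparameterize_dbb(dbb)
  expect_equal(fk$weights, dbb$w_kxk, tolerance = 1e-12)
  expect_equal(fk$bias, rep(0, 4), tolerance = 1e-12)

  # randomly initialized block (random running stats): deploy forward equals
  # the literal sum of branch forwards
  dbb <- ilcnn:::ly_dbb(4, 8, 3)
  for (nm in c("bn_kxk", "bn_1x1", "bn_seq1", "bn_seq2", "bn_avg1", "bn_avg2")) {
    bn <- dbb[[nm]]
    bn$gamma <- runif(8, 0.5, 1.5); bn$beta <- rnorm(8, 0, 0.3)
    bn$r_mean <- rnorm(8, 0, 0.5); bn$r_var <- runif(8, 0.2, 2)
  }
  fk <- reparameterize_dbb(dbb)
  for (i in 1:3) {
    x <- array(rnorm(10 * 12 * 4 * 2), c(10, 12, 4, 2))
    expect_lt(max(abs(conv2d(x, fk$weights, fk$bias, pad = 1) -
                      ref_dbb_forward(dbb, x))), 1e-9)
  }
})

test_that("fusion equivalence holds across random configurations", {
  set.seed(6)
  for (rep in 1:20) {
    cin <- sample(1:5, 1); cout <- sample(1:6, 1)
    K <- sample(c(1L, 3L, 5L), 1)
    dbb <- ilcnn:::ly_dbb(cin, cout, K)
    # populate statistics by running a couple of training forwards
    for (i in 1:2)
      invisible(ilcnn:::fwd(dbb, array(rnorm(8 * 9 * cin * 3), c(8, 9, cin, 3)),
                            training = TRUE))
    fk <- reparameterize_dbb(dbb)
    x <- array(rnorm(8 * 9 * cin * 2), c(8, 9, cin, 2))
    y_train <- ilcnn:::fwd(dbb, x, training = FALSE)
    y_fused <- conv2d(x, fk$weights, fk$bias, pad = (K - 1) %/% 2)
    expect_lt(max(abs(y_train - y_fused)), 1e-9)
    # fused parameter count strictly below train-time count for K > 1
    if (K > 1) {
      train_n <- sum(vapply(ilcnn:::all_params(dbb), function(r)
        as.numeric(length(r$env[[r$name]])), numeric(1)))
      expect_lt(length(fk$weights) + length(fk$bias), train_n)
    }
  }
})

test_that("branch merging is linear in any branch's fused kernel", {
  set.seed(7)
  k1 <- random_kernel(3, 2, 3)
  k2 <- random_kernel(1, 2, 3)
  k2_scaled <- fused_kernel(5 * k2$weights, 5 * k2$bias)
  m1 <- merge_parallel_branches(list(k1, k2), 3)
  m5 <- merge_parallel_branches(list(k1, k2_scaled), 3)
  delta <- merge_parallel_branches(list(k2), 3)
  expect_equal(m5$weights, m1$weights + 4 * delta$weights, tolerance = 1e-12)
  expect_equal(m5$bias, m1$bias + 4 * delta$bias, tolerance = 1e-12)
})
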