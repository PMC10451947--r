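# Coordinate attention: directional pooling and the gated forward pass.

test_that("directional_pool averages along each axis", {
  const <- array(3.5, c(4, 5, 2, 1))
  zp <- directional_pool(const)
  expect_true(all(zp$z_h == 3.5) && all(zp$z_w == 3.5))

  x <- matrix(0, 4, 4); x[1, ] <- 1
  zp <- directional_pool(x)
  expect_equal(as.vector(zp$z_h), c(1, 0, 0, 0))
  expect_equal(as.vector(zp$z_w), rep(0.25, 4))

  set.seed(21)
  x <- array(rnorm(6 * 7 * 3 * 2), c(6, 7, 3, 2))
  zp <- directional_pool(x)
  for (c in 1:3) for (n in 1:2) {
    expect_lt(max(abs(zp$z_h[, c, n] - rowMeans(x[, , c, n]))), 1e-7)
    expect_lt(max(abs(zp$z_w[, c, n] - colMeans(x[, , c, n]))), 1e-7)
  }
})

test_that("coam_forward gates the input per row and column", {
  set.seed(22)
  coam <- coam_init(coam_config(8))
  x <- array(runif(6 * 5 * 8 * 2), c(6, 5, 8, 2))

  # zero weights and biases everywhere -> both gates are sigmoid(0) = 0.5
  zero <- coam_init(coam_config(8))
  for (nm in c("w_enc", "b_enc", "w_h", "b_h", "w_w", "b_w")) zero[[nm]][] <- 0
  zero$bn$gamma[] <- 0; zero$bn$beta[] <- 0
  expect_equal(coam_forward(x, zero), 0.25 * x,
               tolerance = 1e-12, ignore_attr = TRUE)

  # gates strictly inside (0, 1): output attenuates every nonzero entry
  y <- coam_forward(x, coam)
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) < abs(x) | x == 0))
  g <- attr(y, "gates")
  expect_true(all(g$gh > 0 & g$gh < 1) && all(g$gw > 0 & g$gw < 1))

  expect_error(coam_forward(array(0, c(4, 4, 3, 1)), coam), "channels")
})

test_that("coam_forward matches a straight-line reference composition", {
  set.seed(23)
  cfg <- coam_config(16, reduction = 32, min_mid = 8)
  coam <- coam_init(cfg)
  x <- array(rnorm(5 * 9 * 16 * 2), c(5, 9, 16, 2))
  y <- coam_forward(x, coam)

  H <- 5; W <- 9; C <- 16; mid <- coam$mid
  hsw <- function(v) v * pmin(pmax(v + 3, 0), 6) / 6
  sig <- function(v) 1 / (1 + exp(-v))
  enc <- matrix(coam$w_enc[1, 1, , ], C, mid)
  wh <- matrix(coam$w_h[1, 1, , ], mid, C)
  ww <- matrix(coam$w_w[1, 1, , ], mid, C)
  ref <- array(0, dim(x))
  for (n in 1:2) {
    zh <- t(sapply(1:H, function(h) colMeans(matrix(x[h, , , n], W, C))))
    zw <- t(sapply(1:W, function(w) colMeans(matrix(x[, w, , n], H, C))))
    u <- rbind(zh, zw)                       # (H+W) x C
    t1 <- sweep(u %*% enc, 2, coam$b_enc, "+")
    t2 <- sweep(sweep(t1, 2, coam$bn$r_mean), 2,
                sqrt(coam$bn$r_var + coam$bn$eps), "/")
    t2 <- sweep(sweep(t2, 2, coam$bn$gamma, "*"), 2, coam$bn$beta, "+")
    a <- hsw(t2)
    gh <- sig(sweep(a[1:H, , drop = FALSE] %*% wh, 2, coam$b_h, "+"))
    gw <- sig(sweep(a[H + 1:W, , drop = FALSE] %*% ww, 2, coam$b_w, "+"))
    for (c in 1:C) ref[, , c, n] <- x[, , c, n] * outer(gh[, c], gw[, c])
  }
  expect_lt(max(abs(y - ref)), 1e-6)
})

test_that("spatially constant input gives constant gate vectors", {
  set.seed(24)
  coam <- coam_init(coam_config(8))
  x <- array(2, c(7, 9, 8, 1))
  y <- coam_forward(x, coam)
  g <- attr(y, "gates")
  for (c in 1:8) {
    expect_lt(diff(range(g$gh[, c, 1])), 1e-12)
    expect_lt(diff(range(g$gw[, c, 1])), 1e-12)
  }
})
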