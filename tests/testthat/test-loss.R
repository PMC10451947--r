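# Elastic angular-margin softmax loss on normalized embeddings.

test_that("sample_margin draws reproducible Gaussians around m", {
  expect_identical(sample_margin(0.5, 0, 10), rep(0.5, 10))
  set.seed(31); a <- sample_margin(0.5, 0.05, 100)
  set.seed(31); b <- sample_margin(0.5, 0.05, 100)
  expect_identical(a, b)
  set.seed(32)
  draws <- sample_margin(0.5, 0.05, 1e5)
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.05 / sqrt(1e5))
})

test_that("aligned/orthogonal toy geometry gives the closed-form loss", {
  # x aligned with its class weight, the other class orthogonal, s = 1,
  # no margin: L = -log(e / (e + 1))
  x <- matrix(c(1, 0), 1, 2)
  w <- rbind(c(1, 0), c(0, 1))
  L <- eml_loss(x, 1L, w, eml_config(n = 2, s = 1, m = 0, sigma = 0))
  expect_equal(L, -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  expect_equal(round(L, 4), 0.3133)
})

test_that("sigma = 0 reduces to the additive-angular-margin loss", {
  set.seed(33)
  for (rep in 1:5) {
    e <- matrix(rnorm(8 * 16), 8, 16)
    w <- matrix(rnorm(5 * 16), 5, 16)
    labels <- sample(1:5, 8, replace = TRUE)
    L <- eml_loss(e, labels, w, eml_config(n = 5, s = 64, m = 0.5, sigma = 0))
    expect_lt(abs(L - ref_margin_loss(e, labels, w, 64, 0.5)), 1e-6)
  }
})

test_that("the loss is non-negative and non-decreasing in the margin", {
  set.seed(34)
  e <- matrix(rnorm(6 * 8), 6, 8)
  w <- matrix(rnorm(4 * 8), 4, 8)
  labels <- sample(1:4, 6, replace = TRUE)
  prev <- -Inf
  for (m in c(0, 0.1, 0.3, 0.5, 0.8)) {
    L <- eml_loss(e, labels, w, eml_config(n = 4, s = 8, m = m, sigma = 0))
    expect_gte(L, 0)
    expect_gte(L, prev - 1e-12)
    prev <- L
  }
})

test_that("normalization absorbs any positive rescaling of the inputs", {
  set.seed(35)
  e <- matrix(rnorm(5 * 12), 5, 12)
  w <- matrix(rnorm(7 * 12), 7, 12)
  labels <- sample(1:7, 5, replace = TRUE)
  cfg <- eml_config(n = 7)
  margins <- sample_margin(cfg$m, cfg$sigma, 5)
  L1 <- eml_loss(e, labels, w, cfg, margins = margins)
  L2 <- eml_loss(17.3 * e, labels, 0.01 * w, cfg, margins = margins)
  expect_equal(L1, L2, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  e <- matrix(rnorm(3 * 4), 3, 4)
  w <- matrix(rnorm(2 * 4), 2, 4)
  cfg <- eml_config(n = 2)
  e0 <- e; e0[2, ] <- 0
  expect_error(eml_loss(e0, c(1L, 2L, 1L), w, cfg), "zero-norm")
  expect_error(eml_loss(e, c(1L, 3L, 1L), w, cfg), "out of range")
  expect_error(eml_config(n = 2, s = -1))
  expect_error(eml_config(n = 2, m = 4))
})
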