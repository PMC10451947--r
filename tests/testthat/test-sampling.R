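# Adaptive polyphase sampling: decomposition, norm-based phase selection,
# and shift behaviour of the 2x downsampling.

test_that("polyphase_decompose partitions the input", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-wise
  comps <- polyphase_decompose(x)
  expect_equal(vapply(comps, function(z) z[1, 1, 1, 1], numeric(1)),
               c(1, 2, 3, 4))

  const <- matrix(7, 4, 6)
  comps <- polyphase_decompose(const)
  for (z in comps) expect_true(all(z == 7))

  set.seed(11)
  x <- array(rnorm(6 * 8 * 3 * 2), c(6, 8, 3, 2))
  comps <- polyphase_decompose(x)
  rebuilt <- array(0, dim(x))
  rebuilt[seq(1, 6, 2), seq(1, 8, 2), , ] <- comps[[1]]
  rebuilt[seq(1, 6, 2), seq(2, 8, 2), , ] <- comps[[2]]
  rebuilt[seq(2, 6, 2), seq(1, 8, 2), , ] <- comps[[3]]
  rebuilt[seq(2, 6, 2), seq(2, 8, 2), , ] <- comps[[4]]
  expect_identical(rebuilt, x)
})

test_that("odd extents are padded bottom/right before decomposition", {
  x <- matrix(rnorm(25), 5, 5)
  out <- aps_downsample(x)
  expect_equal(dim(out)[1:2], c(3L, 3L))
})

test_that("select_phase picks the maximal Lp norm with raster tie-break", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  sel <- select_phase(polyphase_decompose(x), aps_config(p = 2))
  expect_equal(sel$norms, c(1, 2, 3, 4))
  expect_equal(sel$phase_index, c(1L, 1L))
  expect_equal(as.vector(sel$component), 4)

  sel <- select_phase(polyphase_decompose(matrix(5, 4, 4)))
  expect_equal(sel$phase_index, c(0L, 0L))  # tie -> lowest raster phase

  # norms match a direct computation on a random map
  set.seed(12)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  comps <- polyphase_decompose(x)
  sel <- select_phase(comps, aps_config(p = 2))
  direct <- vapply(comps, function(z) sqrt(sum(z^2)), numeric(1))
  expect_equal(sel$norms, direct, tolerance = 1e-6)
  expect_equal(sel$component, comps[[which.max(direct)]])

  bad <- comps; bad[[2]][1] <- NaN
  expect_error(select_phase(bad), "NaN")
})

test_that("worked 2x2 shift case: the retained value survives translation", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  xs <- matrix(c(2, 4, 1, 3), 2, 2)  # one-column circular shift
  expect_equal(as.vector(aps_downsample(x)), 4)
  expect_equal(as.vector(aps_downsample(xs)), 4)
})

test_that("unit circular shifts preserve the selected value multiset", {
  set.seed(13)
  for (rep in 1:10) {
    x <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1))
    base <- sort(as.vector(aps_downsample(x)))
    for (sh in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 0))) {
      shifted <- aps_downsample(circ_shift(x, sh[1], sh[2]))
      expect_equal(sort(as.vector(shifted)), base)
    }
  }
})

test_that("even circular shifts commute exactly with APS downsampling", {
  set.seed(14)
  x <- array(rnorm(12 * 12 * 3), c(12, 12, 3, 1))
  y <- aps_downsample(x)
  for (sh in list(c(2, 0), c(0, 2), c(4, 2))) {
    ys <- aps_downsample(circ_shift(x, sh[1], sh[2]))
    expect_identical(as.vector(circ_shift(array(y, dim(y)), sh[1] / 2, sh[2] / 2)),
                     as.vector(array(ys, dim(ys))))
  }
})

test_that("max-pool replacement applies stride-1 pooling before selection", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  out <- aps_downsample(x, max_pool = TRUE)
  expect_equal(as.vector(out), 4)
  # pooled map has the max in every window, so all phases tie at 4 for the
  # interior; output keeps the input's spatial halving contract
  x2 <- matrix(rnorm(36), 6, 6)
  expect_equal(dim(aps_downsample(x2, max_pool = TRUE))[1:2], c(3L, 3L))
})
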