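# Diverse branch block (DBB): train-time four-branch convolution and the
# exact algebra that collapses it into a single convolution for deployment.
#
# All transforms here are closed-form and exact: a convolution followed by a
# (frozen-statistics) batch norm is itself an affine convolution; parallel
# branches of odd kernel size <= K sum into one K x K kernel after centred
# zero-padding; and a 1x1 convolution followed by a K x K convolution is a
# single K x K convolution once the intermediate map is padded with the 1x1
# stage's bias rather than with zeros.

#' Convolution layer specification
#'
#' @param in_channels,out_channels positive integers.
#' @param kernel_size odd positive integer K.
#' @param stride positive integer.
#' @param padding non-negative integer; defaults to `(K - 1) / 2`
#'   (shape-preserving).
#' @param has_bias does the convolution carry a bias term?
#' @return an object of class `conv_spec`.
#' @export
conv_spec <- function(in_channels, out_channels, kernel_size,
                      stride = 1L, padding = (kernel_size - 1L) %/% 2L,
                      has_bias = TRUE) {
  stopifnot(in_channels >= 1, out_channels >= 1,
            kernel_size >= 1, kernel_size %% 2 == 1,
            stride >= 1, padding >= 0)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride),
                 padding = as.integer(padding),
                 has_bias = isTRUE(has_bias)),
            class = "conv_spec")
}

#' Batch-normalization statistics
#'
#' Per-channel affine parameters and running moments of a batch-norm layer,
#' as needed to fold the layer into a preceding convolution.
#'
#' @param gamma,beta per-channel scale and shift.
#' @param mean,var per-channel running mean and variance (`var >= 0`).
#' @param eps small positive stabilizer added to the variance.
#' @return an object of class `bn_stats`.
#' @export
bn_stats <- function(gamma, beta, mean, var, eps = 1e-5) {
  n <- length(gamma)
  if (!all(lengths(list(beta, mean, var)) == n))
    stop("bn_stats: gamma, beta, mean, var must have equal length")
  if (anyNA(c(gamma, beta, mean, var)) )
    stop("bn_stats: statistics not populated (NA)")
  if (any(var < 0)) stop("bn_stats: negative variance")
  if (eps <= 0) stop("bn_stats: eps must be positive")
  structure(list(gamma = as.double(gamma), beta = as.double(beta),
                 mean = as.double(mean), var = as.double(var),
                 eps = as.double(eps)),
            class = "bn_stats")
}

#' Fused convolution kernel
#'
#' A plain `(weights, bias)` pair for a single K x K convolution: the target
#' of every reparameterization transform.
#'
#' @param weights array `c(K, K, Cin, Cout)`.
#' @param bias numeric length `Cout`; defaults to zeros.
#' @return an object of class `fused_kernel`.
#' @export
fused_kernel <- function(weights, bias = NULL) {
  d <- dim(weights)
  stopifnot(length(d) == 4L, d[1] == d[2])
  if (is.null(bias)) bias <- numeric(d[4])
  stopifnot(length(bias) == d[4])
  if (!all(is.finite(weights)) || !all(is.finite(bias)))
    stop("fused_kernel: non-finite entries")
  structure(list(weights = weights, bias = as.double(bias)),
            class = "fused_kernel")
}

kernel_size_of <- function(k) dim(k$weights)[1]

#' Fold a batch norm into a convolution
#'
#' Returns the kernel `K'` with `conv(x; K') == BN(conv(x; K))` for all `x`
#' (frozen statistics): `W'_c = W_c * gamma_c / sqrt(var_c + eps)` and
#' `b'_c = beta_c + (b_c - mean_c) * gamma_c / sqrt(var_c + eps)`.
#'
#' @param kernel a [fused_kernel()].
#' @param bn a [bn_stats()] whose channel count equals the kernel's
#'   out-channel count.
#' @return a [fused_kernel()].
#' @export
fuse_conv_bn <- function(kernel, bn) {
  d <- dim(kernel$weights)
  if (length(bn$gamma) != d[4])
    stop("fuse_conv_bn: BN channel count (", length(bn$gamma),
         ") != kernel out_channels (", d[4], ")")
  denom <- bn$var + bn$eps
  if (any(denom <= 0)) stop("fuse_conv_bn: var + eps must be positive")
  scale <- bn$gamma / sqrt(denom)
  w <- kernel$weights * rep(scale, each = prod(d[1:3]))
  b <- bn$beta + (kernel$bias - bn$mean) * scale
  fused_kernel(w, b)
}

#' Sum parallel convolution branches into one kernel
#'
#' Each branch kernel (odd size `<= k_target`) is zero-padded symmetrically
#' to `k_target` x `k_target`; weights and biases are then summed. The fused
#' forward equals the sum of the branch forwards when all branches run at
#' the same stride with shape-preserving padding.
#'
#' @param kernels list of [fused_kernel()]s sharing in/out channel counts.
#' @param k_target odd target kernel size.
#' @return a [fused_kernel()] of size `k_target`.
#' @export
merge_parallel_branches <- function(kernels, k_target) {
  stopifnot(length(kernels) >= 1, k_target %% 2 == 1)
  d0 <- dim(kernels[[1]]$weights)
  w <- array(0, c(k_target, k_target, d0[3], d0[4]))
  b <- numeric(d0[4])
  for (k in kernels) {
    d <- dim(k$weights)
    if (d[1] %% 2 == 0 || d[1] > k_target)
      stop("merge_parallel_branches: branch kernel size must be odd and <= k_target")
    if (d[3] != d0[3] || d[4] != d0[4])
      stop("merge_parallel_branches: branches disagree on channel counts")
    off <- (k_target - d[1]) %/% 2
    idx <- off + seq_len(d[1])
    w[idx, idx, , ] <- w[idx, idx, , , drop = FALSE] + k$weights
    b <- b + k$bias
  }
  fused_kernel(w, b)
}

#' Collapse a 1x1 -> KxK convolution chain into one KxK kernel
#'
#' The merged kernel `W[kh,kw,ci,co] = sum_cm k2[kh,kw,cm,co] * k1[ci,cm]`,
#' with bias `b2 + (sum over taps of k2) applied to k1's bias`. Exact
#' equivalence holds under the padding convention in which the 1x1 stage
#' runs unpadded and its output map is then constant-padded with the 1x1
#' bias (per channel) before the K x K stage — i.e. padding is compensated
#' after the pointwise stage, not before it.
#'
#' @param k1 a 1x1 [fused_kernel()] (Cin -> Cmid).
#' @param k2 a KxK [fused_kernel()] (Cmid -> Cout).
#' @return a KxK [fused_kernel()] (Cin -> Cout).
#' @export
merge_sequential_1x1_kxk <- function(k1, k2) {
  d1 <- dim(k1$weights); d2 <- dim(k2$weights)
  if (d1[1] != 1) stop("merge_sequential_1x1_kxk: first kernel must be 1x1")
  if (d1[4] != d2[3])
    stop("merge_sequential_1x1_kxk: channel chain mismatch (",
         d1[4], " -> ", d2[3], ")")
  K <- d2[1]
  m1 <- matrix(k1$weights[1, 1, , ], nrow = d1[3], ncol = d1[4])  # Cin x Cmid
  w <- array(0, c(K, K, d1[3], d2[4]))
  for (kh in seq_len(K))
    for (kw in seq_len(K))
      w[kh, kw, , ] <- m1 %*% matrix(k2$weights[kh, kw, , ],
                                     nrow = d2[3], ncol = d2[4])
  # every K x K tap sees the (padded-in) bias of the 1x1 stage
  tap_sum <- apply(k2$weights, 4, function(wco) colSums(matrix(wco, ncol = d2[3])))
  # tap_sum is Cmid x Cout after the reshape below
  tap_sum <- matrix(tap_sum, nrow = d2[3], ncol = d2[4])
  b <- k2$bias + as.vector(crossprod(tap_sum, k1$bias))
  fused_kernel(w, b)
}

#' Express K x K average pooling as a convolution kernel
#'
#' @param k odd pooling window size.
#' @param channels channel count (pooling acts per channel).
#' @return a [fused_kernel()] with `1/k^2` at every spatial tap of the
#'   diagonal (in-channel == out-channel) and zero elsewhere; zero bias.
#' @export
avgpool_as_conv <- function(k, channels) {
  stopifnot(k >= 1, k %% 2 == 1, channels >= 1)
  w <- array(0, c(k, k, channels, channels))
  for (c in seq_len(channels)) w[, , c, c] <- 1 / k^2
  fused_kernel(w)
}

#' Fuse a trained diverse branch block into a single convolution
#'
#' Collapses the four train-time branches (KxK+BN; 1x1+BN; 1x1+BN -> KxK+BN;
#' 1x1+BN -> KxK average pool + BN) into one K x K convolution with bias,
#' using the running batch-norm statistics. Only legal with frozen (running)
#' statistics, i.e. for a block in evaluation mode.
#'
#' @param dbb a DBB layer created by [ly_dbb()].
#' @return a [fused_kernel()] whose forward equals the sum of the four
#'   branch forwards (evaluation mode) for every input.
#' @export
reparameterize_dbb <- function(dbb) {
  stopifnot(inherits(dbb, "ly_dbb"))
  K <- dbb$k
  f_kxk <- fuse_conv_bn(fused_kernel(dbb$w_kxk), bn_snapshot(dbb$bn_kxk))
  f_1x1 <- fuse_conv_bn(fused_kernel(dbb$w_1x1), bn_snapshot(dbb$bn_1x1))
  f_seq <- merge_sequential_1x1_kxk(
    fuse_conv_bn(fused_kernel(dbb$w_seq1), bn_snapshot(dbb$bn_seq1)),
    fuse_conv_bn(fused_kernel(dbb$w_seq2), bn_snapshot(dbb$bn_seq2)))
  f_avg <- merge_sequential_1x1_kxk(
    fuse_conv_bn(fused_kernel(dbb$w_avg1), bn_snapshot(dbb$bn_avg1)),
    fuse_conv_bn(avgpool_as_conv(K, dbb$out_ch), bn_snapshot(dbb$bn_avg2)))
  merge_parallel_branches(list(f_kxk, f_1x1, f_seq, f_avg), K)
}
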