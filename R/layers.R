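# Minimal layer framework: each layer is an environment holding parameters
# (`<name>`), accumulated gradients (`g_<name>`), and forward caches. Layers
# implement the generics fwd() / bwd(); composite layers list their children
# in $sublayers so parameters can be collected recursively.

new_module <- function(class, trainable = character(), sublayers = character()) {
  e <- new.env(parent = emptyenv())
  e$trainable <- trainable
  e$sublayers <- sublayers
  class(e) <- c(class, "ilcnn_module")
  e
}

fwd <- function(m, x, training = FALSE, ...) UseMethod("fwd")
bwd <- function(m, gy, ...) UseMethod("bwd")

#' @export
print.ilcnn_module <- function(x, ...) {
  cat("<", class(x)[1], "> trainable:", paste(x$trainable, collapse = ", "), "\n")
  invisible(x)
}

# Recursively collect (env, field) references for every trainable parameter.
all_params <- function(m) {
  out <- lapply(m$trainable, function(nm) list(env = m, name = nm))
  for (s in m$sublayers) out <- c(out, all_params(m[[s]]))
  out
}

clear_caches <- function(m) {
  for (nm in ls(m)) if (startsWith(nm, "cache_")) m[[nm]] <- NULL
  for (s in m$sublayers) clear_caches(m[[s]])
  invisible(m)
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

## ---- plain convolution -----------------------------------------------------

ly_conv <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    bias = TRUE) {
  m <- new_module("ly_conv", trainable = if (bias) c("w", "b") else "w")
  m$in_ch <- in_ch; m$out_ch <- out_ch; m$k <- as.integer(k)
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$has_bias <- bias
  m$w <- he_init(k, in_ch, out_ch)
  if (bias) m$b <- numeric(out_ch)
  m
}

#' @export
fwd.ly_conv <- function(m, x, training = FALSE, ...) {
  if (training) m$cache_x <- x else m$cache_x <- NULL
  m$cache_xdim <- dim(x)
  conv2d(x, m$w, if (m$has_bias) m$b else NULL, m$stride, m$pad)
}

#' @export
bwd.ly_conv <- function(m, gy, ...) {
  g <- conv2d_backward(m$cache_x, m$w, gy, m$stride, m$pad)
  m$g_w <- if (is.null(m$g_w)) g$gw else m$g_w + g$gw
  if (m$has_bias) m$g_b <- if (is.null(m$g_b)) g$gb else m$g_b + g$gb
  g$gx
}

# Replace a conv's parameters with a fused kernel (deployment path).
conv_from_fused <- function(fk, stride = 1L) {
  d <- dim(fk$weights)
  m <- ly_conv(d[3], d[4], d[1], stride = stride, bias = TRUE)
  m$w <- fk$weights
  m$b <- fk$bias
  m
}

## ---- batch normalization ---------------------------------------------------

ly_bn <- function(channels, eps = 1e-5, momentum = 0.1) {
  m <- new_module("ly_bn", trainable = c("gamma", "beta"))
  m$channels <- as.integer(channels)
  m$eps <- eps; m$momentum <- momentum
  m$gamma <- rep(1, channels); m$beta <- numeric(channels)
  m$r_mean <- numeric(channels); m$r_var <- rep(1, channels)
  m
}

bn_snapshot <- function(m) bn_stats(m$gamma, m$beta, m$r_mean, m$r_var, m$eps)

# per-channel fused bias of BN acting on zero input: what the BN-and-pad
# construction pads the intermediate map with (uses the statistics of the
# current forward pass: batch in training, running in evaluation)
bn_pad_bias <- function(m) {
  m$beta - m$cache_mu * m$gamma / sqrt(m$cache_var + m$eps)
}

#' @export
fwd.ly_bn <- function(m, x, training = FALSE, ...) {
  d <- dim(x)
  stopifnot(d[3] == m$channels)
  n_per_ch <- prod(d[c(1, 2, 4)])
  if (training) {
    mo <- cpp_channel_moments(x, d)
    mu <- mo$sum / n_per_ch
    va <- pmax(mo$sumsq / n_per_ch - mu^2, 0)
    ub <- if (n_per_ch > 1) n_per_ch / (n_per_ch - 1) else 1
    m$r_mean <- (1 - m$momentum) * m$r_mean + m$momentum * mu
    m$r_var  <- (1 - m$momentum) * m$r_var  + m$momentum * va * ub
  } else {
    mu <- m$r_mean; va <- m$r_var
  }
  inv_sd <- 1 / sqrt(va + m$eps)
  m$cache_mu <- mu; m$cache_var <- va
  if (training) {
    pair <- cpp_bn_forward_pair(x, d, mu, inv_sd, m$gamma, m$beta)
    m$cache_xhat <- pair$xhat
    m$cache_inv_sd <- inv_sd
    m$cache_n <- n_per_ch
    pair$y
  } else {
    scale <- m$gamma * inv_sd
    cpp_channel_affine(x, d, scale, m$beta - mu * scale)
  }
}

#' @export
bwd.ly_bn <- function(m, gy, ...) {
  d <- dim(gy)
  xhat <- m$cache_xhat
  n <- m$cache_n
  s <- cpp_bn_backward_sums(gy, xhat, d)
  g_beta <- s$sum_g
  g_gamma <- s$sum_gx
  m$g_gamma <- if (is.null(m$g_gamma)) g_gamma else m$g_gamma + g_gamma
  m$g_beta  <- if (is.null(m$g_beta))  g_beta  else m$g_beta + g_beta
  cpp_bn_backward_apply(gy, xhat, d, m$gamma * m$cache_inv_sd,
                        g_beta / n, g_gamma / n)
}

## ---- activations -----------------------------------------------------------

ly_relu <- function() new_module("ly_relu")

#' @export
fwd.ly_relu <- function(m, x, training = FALSE, ...) {
  y <- cpp_relu_forward(x)
  if (training) m$cache_y <- y
  y
}

#' @export
bwd.ly_relu <- function(m, gy, ...) cpp_relu_backward(gy, m$cache_y)

hswish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6
hswish_grad <- function(x) ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6))
sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- diverse branch block --------------------------------------------------

# Train-time structure (all convolutions bias-free, each branch BN-terminated):
#   (a) KxK conv -> BN
#   (b) 1x1 conv -> BN
#   (c) 1x1 conv -> BN -> pad with BN bias -> KxK conv -> BN
#   (d) 1x1 conv -> BN -> pad with BN bias -> KxK avg pool (fixed conv) -> BN
# Branch outputs are summed. Padding the intermediate maps of (c)/(d) with the
# BN's zero-input output (instead of zeros) is what makes the closed-form
# fusion exact at the borders.
ly_dbb <- function(in_ch, out_ch, k = 3L) {
  stopifnot(k %% 2 == 1)
  m <- new_module("ly_dbb",
                  trainable = c("w_kxk", "w_1x1", "w_seq1", "w_seq2", "w_avg1"),
                  sublayers = c("bn_kxk", "bn_1x1", "bn_seq1", "bn_seq2",
                                "bn_avg1", "bn_avg2"))
  m$in_ch <- in_ch; m$out_ch <- out_ch; m$k <- as.integer(k)
  m$pad <- (k - 1L) %/% 2L
  m$w_kxk  <- he_init(k, in_ch, out_ch)
  m$w_1x1  <- he_init(1, in_ch, out_ch)
  m$w_seq1 <- he_init(1, in_ch, out_ch)   # internal width = out_ch
  m$w_seq2 <- he_init(k, out_ch, out_ch)
  m$w_avg1 <- he_init(1, in_ch, out_ch)
  for (nm in c("bn_kxk", "bn_1x1", "bn_seq1", "bn_seq2", "bn_avg1", "bn_avg2"))
    m[[nm]] <- ly_bn(out_ch)
  m
}

#' @export
fwd.ly_dbb <- function(m, x, training = FALSE, ...) {
  p <- m$pad; oc <- m$out_ch
  if (training) m$cache_x <- x
  m$cache_xdim <- dim(x)
  y1 <- fwd(m$bn_kxk, conv2d(x, m$w_kxk, NULL, 1L, p), training)
  # the three pointwise stages share their input: run them as one GEMM
  wcat <- array(c(m$w_1x1, m$w_seq1, m$w_avg1), c(1L, 1L, m$in_ch, 3L * oc))
  ycat <- conv2d(x, wcat, NULL, 1L, 0L)
  y2 <- fwd(m$bn_1x1, ycat[, , seq_len(oc), , drop = FALSE], training)
  z <- fwd(m$bn_seq1, ycat[, , oc + seq_len(oc), , drop = FALSE], training)
  zp <- pad_spatial(z, p, bn_pad_bias(m$bn_seq1))
  if (training) m$cache_zp <- zp
  y3 <- fwd(m$bn_seq2, conv2d(zp, m$w_seq2, NULL, 1L, 0L), training)
  a <- fwd(m$bn_avg1, ycat[, , 2L * oc + seq_len(oc), , drop = FALSE], training)
  ap <- pad_spatial(a, p, bn_pad_bias(m$bn_avg1))
  if (training) m$cache_apdim <- dim(ap)
  y4 <- fwd(m$bn_avg2, cpp_avgpool_s1_valid(ap, dim(ap), m$k), training)
  y1 + y2 + y3 + y4
}

# Gradient of a branch whose intermediate map was padded with the BN bias
# b_c = beta_c - mu_c * gamma_c / sigma_c. Three contributions:
#   (1) the interior cells flow through the BN backward as usual;
#   (2) the pad-cell sums s_c feed beta and gamma directly;
#   (3) in training mode mu/var are batch statistics of the BN input z, so
#       the pad value also moves with z:
#       dL/dz_i += (s_c * gamma_c / (sigma_c n)) * (mu_c * xhat_i / sigma_c - 1).
# Returns the interior gradient and the per-channel pad sums; the caller adds
# pad_stats_grad() after the BN backward.
unpad_with_bias_grad <- function(gzp, p, bn) {
  d <- dim(gzp)
  gz <- gzp[p + seq_len(d[1] - 2 * p), p + seq_len(d[2] - 2 * p), , , drop = FALSE]
  s_pad <- cpp_channel_moments(gzp, d)$sum -
    cpp_channel_moments(gz, dim(gz))$sum
  bn$g_beta <- if (is.null(bn$g_beta)) s_pad else bn$g_beta + s_pad
  gg <- s_pad * (-bn$cache_mu / sqrt(bn$cache_var + bn$eps))
  bn$g_gamma <- if (is.null(bn$g_gamma)) gg else bn$g_gamma + gg
  list(gz = gz, s_pad = s_pad)
}

# term (3) above, evaluated on the BN's cached normalized input
pad_stats_grad <- function(bn, s_pad) {
  coef <- s_pad * bn$gamma * bn$cache_inv_sd / bn$cache_n
  cpp_channel_affine(bn$cache_xhat, dim(bn$cache_xhat),
                     coef * bn$cache_mu * bn$cache_inv_sd, -coef)
}

#' @export
bwd.ly_dbb <- function(m, gy, ...) {
  p <- m$pad; x <- m$cache_x; oc <- m$out_ch
  # branch (a)
  g1 <- bwd(m$bn_kxk, gy)
  pr <- conv2d_backward(x, m$w_kxk, g1, 1L, p)
  m$g_w_kxk <- if (is.null(m$g_w_kxk)) pr$gw else m$g_w_kxk + pr$gw
  gx <- pr$gx
  # branch (b) gradient at the pointwise stage
  g2 <- bwd(m$bn_1x1, gy)
  # branch (c)
  g3 <- bwd(m$bn_seq2, gy)
  pr <- conv2d_backward(m$cache_zp, m$w_seq2, g3, 1L, 0L)
  m$g_w_seq2 <- if (is.null(m$g_w_seq2)) pr$gw else m$g_w_seq2 + pr$gw
  up <- unpad_with_bias_grad(pr$gx, p, m$bn_seq1)
  gz <- bwd(m$bn_seq1, up$gz) + pad_stats_grad(m$bn_seq1, up$s_pad)
  # branch (d)
  g4 <- bwd(m$bn_avg2, gy)
  gap_ <- cpp_avgpool_s1_valid_backward(g4, dim(g4), m$cache_apdim, m$k)
  up <- unpad_with_bias_grad(gap_, p, m$bn_avg1)
  ga <- bwd(m$bn_avg1, up$gz) + pad_stats_grad(m$bn_avg1, up$s_pad)
  # the three pointwise branches share x: one packed backward GEMM, whose
  # input gradient is already the sum over the three branches
  d <- dim(g2)
  gcat <- array(0, c(d[1], d[2], 3L * oc, d[4]))
  gcat[, , seq_len(oc), ] <- g2
  gcat[, , oc + seq_len(oc), ] <- gz
  gcat[, , 2L * oc + seq_len(oc), ] <- ga
  wcat <- array(c(m$w_1x1, m$w_seq1, m$w_avg1), c(1L, 1L, m$in_ch, 3L * oc))
  pr <- conv2d_backward(x, wcat, gcat, 1L, 0L)
  gwc <- pr$gw
  m$g_w_1x1 <- if (is.null(m$g_w_1x1)) gwc[, , , seq_len(oc), drop = FALSE] else
    m$g_w_1x1 + gwc[, , , seq_len(oc), drop = FALSE]
  m$g_w_seq1 <- if (is.null(m$g_w_seq1)) gwc[, , , oc + seq_len(oc), drop = FALSE] else
    m$g_w_seq1 + gwc[, , , oc + seq_len(oc), drop = FALSE]
  m$g_w_avg1 <- if (is.null(m$g_w_avg1)) gwc[, , , 2L * oc + seq_len(oc), drop = FALSE] else
    m$g_w_avg1 + gwc[, , , 2L * oc + seq_len(oc), drop = FALSE]
  gx + pr$gx
}

## ---- coordinate attention --------------------------------------------------

ly_coam <- function(channels, reduction = 32L, min_mid = 8L) {
  mid <- max(as.integer(min_mid), channels %/% as.integer(reduction))
  m <- new_module("ly_coam",
                  trainable = c("w_enc", "b_enc", "w_h", "b_h", "w_w", "b_w"),
                  sublayers = "bn")
  m$channels <- as.integer(channels); m$mid <- mid
  m$reduction <- as.integer(reduction)
  m$w_enc <- he_init(1, channels, mid); m$b_enc <- numeric(mid)
  m$bn <- ly_bn(mid)
  m$w_h <- he_init(1, mid, channels); m$b_h <- numeric(channels)
  m$w_w <- he_init(1, mid, channels); m$b_w <- numeric(channels)
  m
}

#' @export
fwd.ly_coam <- function(m, x, training = FALSE, ...) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  stopifnot(C == m$channels)
  zp <- cpp_dir_pool(x, d)  # z_h: (H, C, N), z_w: (W, C, N)
  u <- array(0, c(1, H + W, C, N))
  u[1, seq_len(H), , ] <- zp$z_h
  u[1, H + seq_len(W), , ] <- zp$z_w
  t1 <- conv2d(u, m$w_enc, m$b_enc)
  t2 <- fwd(m$bn, t1, training)
  a <- hswish(t2)
  ah <- a[, seq_len(H), , , drop = FALSE]
  aw <- a[, H + seq_len(W), , , drop = FALSE]
  gh <- sigmoid(conv2d(ah, m$w_h, m$b_h))  # (1, H, C, N)
  gw <- sigmoid(conv2d(aw, m$w_w, m$b_w))  # (1, W, C, N)
  ghv <- array(gh, c(H, C, N)); gwv <- array(gw, c(W, C, N))
  y <- cpp_gate_apply(x, d, ghv, gwv)
  if (training) {
    m$cache_x <- x; m$cache_u <- u; m$cache_t2 <- t2
    m$cache_ah <- ah; m$cache_aw <- aw
    m$cache_gh <- ghv; m$cache_gw <- gwv
  }
  m$cache_gates <- list(gh = ghv, gw = gwv)
  y
}

#' @export
bwd.ly_coam <- function(m, gy, ...) {
  d <- dim(gy); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gb <- cpp_gate_backward(gy, m$cache_x, d, m$cache_gh, m$cache_gw)
  dgh_lin <- array(gb$dgh * m$cache_gh * (1 - m$cache_gh), c(1, H, C, N))
  dgw_lin <- array(gb$dgw * m$cache_gw * (1 - m$cache_gw), c(1, W, C, N))
  pr <- conv2d_backward(m$cache_ah, m$w_h, dgh_lin, 1L, 0L)
  m$g_w_h <- if (is.null(m$g_w_h)) pr$gw else m$g_w_h + pr$gw
  m$g_b_h <- if (is.null(m$g_b_h)) pr$gb else m$g_b_h + pr$gb
  dah <- pr$gx
  pr <- conv2d_backward(m$cache_aw, m$w_w, dgw_lin, 1L, 0L)
  m$g_w_w <- if (is.null(m$g_w_w)) pr$gw else m$g_w_w + pr$gw
  m$g_b_w <- if (is.null(m$g_b_w)) pr$gb else m$g_b_w + pr$gb
  daw <- pr$gx
  da <- array(0, c(1, H + W, m$mid, N))
  da[, seq_len(H), , ] <- dah
  da[, H + seq_len(W), , ] <- daw
  dt2 <- da * hswish_grad(m$cache_t2)
  dt1 <- bwd(m$bn, dt2)
  pr <- conv2d_backward(m$cache_u, m$w_enc, dt1, 1L, 0L)
  m$g_w_enc <- if (is.null(m$g_w_enc)) pr$gw else m$g_w_enc + pr$gw
  m$g_b_enc <- if (is.null(m$g_b_enc)) pr$gb else m$g_b_enc + pr$gb
  du <- pr$gx
  dzh <- array(du[, seq_len(H), , , drop = FALSE], c(H, C, N))
  dzw <- array(du[, H + seq_len(W), , , drop = FALSE], c(W, C, N))
  cpp_dir_pool_backward_add(gb$gx, d, dzh, dzw)
}

## ---- adaptive polyphase sampling layer -------------------------------------

ly_aps <- function(p = 2) {
  m <- new_module("ly_aps")
  m$p <- p
  m
}

# forward with optional externally imposed per-sample phase (used by the
# residual shortcut so both paths subsample on the same grid)
#' @export
fwd.ly_aps <- function(m, x, training = FALSE, phase = NULL, ...) {
  d <- dim(x)
  xp <- pad_even(x, "zero")
  m$cache_xdim <- d
  m$cache_pdim <- dim(xp)
  dp <- dim(xp)
  H2 <- dp[1] %/% 2L; W2 <- dp[2] %/% 2L; N <- dp[4]
  comps <- decompose_phases(xp)
  if (is.null(phase)) {
    nrm <- vapply(comps, function(cc)
      colSums(abs(matrix(cc, ncol = N))^m$p)^(1 / m$p), numeric(N))
    if (is.null(dim(nrm))) nrm <- matrix(nrm, nrow = N)
    phase <- apply(nrm, 1, which.max)  # ties: lowest raster index
  }
  m$cache_phase <- phase
  y <- array(0, c(H2, W2, dp[3], N))
  for (n in seq_len(N)) y[, , , n] <- comps[[phase[n]]][, , , n]
  y
}

#' @export
bwd.ly_aps <- function(m, gy, ...) {
  dp <- m$cache_pdim; d <- m$cache_xdim
  gx <- array(0, dp)
  off <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  for (n in seq_len(dp[4])) {
    o <- off[[m$cache_phase[n]]]
    gx[seq(1L + o[1], dp[1], by = 2L), seq(1L + o[2], dp[2], by = 2L), , n] <-
      gy[, , , n]
  }
  gx[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
}

aps_phase <- function(m) m$cache_phase

## ---- max pooling (2x2, stride 2; basic-residual baseline only) -------------

ly_maxpool2 <- function() new_module("ly_maxpool2")

#' @export
fwd.ly_maxpool2 <- function(m, x, training = FALSE, ...) {
  m$cache_indim <- dim(x)
  d <- dim(x)
  if (d[1] %% 2 == 1 || d[2] %% 2 == 1) x <- pad_even(x, "zero")
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  cands <- decompose_phases(x)
  stacked <- array(unlist(cands, use.names = FALSE), c(H2 * W2 * d[3] * d[4], 4))
  which4 <- max.col(stacked, ties.method = "first")
  y <- stacked[cbind(seq_len(nrow(stacked)), which4)]
  dim(y) <- c(H2, W2, d[3], d[4])
  if (training) { m$cache_which <- which4; m$cache_dim <- d }
  y
}

#' @export
bwd.ly_maxpool2 <- function(m, gy, ...) {
  d <- m$cache_dim
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  gx <- array(0, d)
  off <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  gv <- as.vector(gy)
  for (ph in 1:4) {
    sel <- m$cache_which == ph
    if (!any(sel)) next
    o <- off[[ph]]
    sub <- array(0, c(H2, W2, d[3], d[4]))
    sub[sel] <- gv[sel]
    gx[seq(1L + o[1], d[1], 2L), seq(1L + o[2], d[2], 2L), , ] <-
      gx[seq(1L + o[1], d[1], 2L), seq(1L + o[2], d[2], 2L), , ] + sub
  }
  di <- m$cache_indim  # crop any even-padding back off
  gx[seq_len(di[1]), seq_len(di[2]), , , drop = FALSE]
}

## ---- global average pooling, dropout, heads --------------------------------

ly_gap <- function() new_module("ly_gap")

#' @export
fwd.ly_gap <- function(m, x, training = FALSE, ...) {
  d <- dim(x)
  m$cache_dim <- d
  matrix(.colMeans(x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
}

#' @export
bwd.ly_gap <- function(m, gy, ...) {
  d <- m$cache_dim
  array(rep(as.vector(gy) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

ly_dropout <- function(rate) {
  m <- new_module("ly_dropout")
  m$rate <- rate
  m
}

#' @export
fwd.ly_dropout <- function(m, x, training = FALSE, ...) {
  if (!training || m$rate <= 0) { m$cache_mask <- NULL; return(x) }
  keep <- 1 - m$rate
  mask <- (matrix(runif(length(x)), nrow(x)) < keep) / keep
  m$cache_mask <- mask
  x * mask
}

#' @export
bwd.ly_dropout <- function(m, gy, ...) {
  if (is.null(m$cache_mask)) gy else gy * m$cache_mask
}

# Cosine classifier head: bias-free weight matrix, rows and input embeddings
# L2-normalized; logits are s * cos(theta). The elastic-margin adjustment is
# applied by the loss, not here.
ly_head_cosine <- function(n_classes, dim, s = 64) {
  m <- new_module("ly_head_cosine", trainable = "W")
  m$n <- as.integer(n_classes); m$d <- as.integer(dim); m$s <- s
  m$W <- matrix(rnorm(n_classes * dim, sd = sqrt(1 / dim)), n_classes, dim)
  m
}

#' @export
fwd.ly_head_cosine <- function(m, x, training = FALSE, ...) {
  # x: d x N matrix of pooled features
  vn <- sqrt(colSums(x^2))
  if (any(vn == 0)) stop("zero-norm embedding cannot be normalized")
  e <- x / rep(vn, each = m$d)
  wn <- sqrt(rowSums(m$W^2))
  if (any(wn == 0)) stop("zero-norm classifier weight cannot be normalized")
  What <- m$W / wn
  cosm <- What %*% e  # n x N
  m$cache_e <- e; m$cache_vn <- vn; m$cache_What <- What; m$cache_wn <- wn
  list(embedding = e, cos = cosm, logits = m$s * cosm)
}

# backward from dL/dcos
#' @export
bwd.ly_head_cosine <- function(m, gy, ...) {
  e <- m$cache_e; What <- m$cache_What
  dWhat <- gy %*% t(e)
  de <- t(What) %*% gy
  gW <- (dWhat - rowSums(dWhat * What) * What) / m$cache_wn
  m$g_W <- if (is.null(m$g_W)) gW else m$g_W + gW
  (de - e * rep(colSums(de * e), each = m$d)) / rep(m$cache_vn, each = m$d)
}

# Plain fully-connected head (softmax baseline for the ablation study).
ly_head_linear <- function(n_classes, dim) {
  m <- new_module("ly_head_linear", trainable = c("W", "b"))
  m$n <- as.integer(n_classes); m$d <- as.integer(dim)
  m$W <- matrix(rnorm(n_classes * dim, sd = sqrt(1 / dim)), n_classes, dim)
  m$b <- numeric(n_classes)
  m
}

#' @export
fwd.ly_head_linear <- function(m, x, training = FALSE, ...) {
  m$cache_x <- x
  vn <- sqrt(colSums(x^2))
  e <- x / rep(pmax(vn, 1e-12), each = m$d)
  list(embedding = e, cos = NULL, logits = m$W %*% x + m$b)
}

#' @export
bwd.ly_head_linear <- function(m, gy, ...) {
  gW <- gy %*% t(m$cache_x)
  m$g_W <- if (is.null(m$g_W)) gW else m$g_W + gW
  gb <- rowSums(gy)
  m$g_b <- if (is.null(m$g_b)) gb else m$g_b + gb
  t(m$W) %*% gy
}

## ---- AdamW optimizer -------------------------------------------------------

adamw <- function(params, lr = 2e-4, beta1 = 0.9, beta2 = 0.999,
                  eps = 1e-8, weight_decay = 0.01) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2
  opt$eps <- eps; opt$wd <- weight_decay
  opt$t <- 0L
  opt$state <- vector("list", length(params))
  class(opt) <- "adamw"
  opt
}

adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    ref <- opt$params[[i]]
    g <- ref$env[[paste0("g_", ref$name)]]
    if (is.null(g)) next
    st <- opt$state[[i]]
    if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
    st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
    st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
    opt$state[[i]] <- st
    p <- ref$env[[ref$name]]
    upd <- (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps) + opt$wd * p
    ref$env[[ref$name]] <- p - opt$lr * upd
  }
  invisible(opt)
}

zero_grads <- function(params) {
  for (ref in params) ref$env[[paste0("g_", ref$name)]] <- NULL
  invisible(NULL)
}
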