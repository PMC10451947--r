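# Independent straight-line reference implementations used as oracles.
# These deliberately use naive loops / direct formulas, not the package's
# GEMM kernels or fusion algebra.

# naive dense cross-correlation, zero padding
ref_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0) {
  d <- dim(x); K <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  H <- d[1] + 2 * pad; W <- d[2] + 2 * pad
  xp <- array(0, c(H, W, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  OH <- (H - K) %/% stride + 1
  OW <- (W - K) %/% stride + 1
  y <- array(0, c(OH, OW, Cout, d[4]))
  for (n in seq_len(d[4]))
    for (co in seq_len(Cout))
      for (oh in seq_len(OH))
        for (ow in seq_len(OW)) {
          acc <- 0
          for (ci in seq_len(Cin))
            acc <- acc + sum(xp[(oh - 1) * stride + seq_len(K),
                                (ow - 1) * stride + seq_len(K), ci, n] *
                             w[, , ci, co])
          y[oh, ow, co, n] <- acc + if (!is.null(b)) b[co] else 0
        }
  y
}

# batch norm with given (frozen) statistics, applied per channel
ref_bn <- function(x, bn) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[3]))
    y[, , c, ] <- bn$gamma[c] * (x[, , c, ] - bn$mean[c]) /
      sqrt(bn$var[c] + bn$eps) + bn$beta[c]
  y
}

random_bn <- function(channels, eps = 1e-5) {
  bn_stats(gamma = runif(channels, 0.5, 1.5),
           beta = rnorm(channels, 0, 0.3),
           mean = rnorm(channels, 0, 0.5),
           var = runif(channels, 0.2, 2),
           eps = eps)
}

random_kernel <- function(k, cin, cout, bias = TRUE) {
  fused_kernel(array(rnorm(k * k * cin * cout), c(k, k, cin, cout)),
               if (bias) rnorm(cout) else NULL)
}

# identity batch-norm statistics (var chosen so var + eps == 1 exactly)
identity_bn <- function(channels, eps = 1e-5) {
  bn_stats(gamma = rep(1, channels), beta = rep(0, channels),
           mean = rep(0, channels), var = rep(1 - eps, channels), eps = eps)
}

# set a ly_bn layer to exact-identity statistics
make_bn_identity <- function(bn_layer) {
  bn_layer$gamma <- rep(1, bn_layer$channels)
  bn_layer$beta <- rep(0, bn_layer$channels)
  bn_layer$r_mean <- rep(0, bn_layer$channels)
  bn_layer$r_var <- rep(1 - bn_layer$eps, bn_layer$channels)
  invisible(bn_layer)
}

# circular shift of the spatial dims of an H x W x C x N array
circ_shift <- function(x, dy, dx) {
  d <- dim(x)
  ri <- ((seq_len(d[1]) - 1 - dy) %% d[1]) + 1
  ci <- ((seq_len(d[2]) - 1 - dx) %% d[2]) + 1
  x[ri, ci, , , drop = FALSE]
}

# evaluation-mode forward of a DBB layer = sum of its four branch forwards,
# written out literally (the fusion oracle)
ref_dbb_forward <- function(dbb, x) {
  p <- dbb$pad; K <- dbb$k
  bnspec <- function(bn) bn_stats(bn$gamma, bn$beta, bn$r_mean, bn$r_var, bn$eps)
  y1 <- ref_bn(ref_conv2d(x, dbb$w_kxk, pad = p), bnspec(dbb$bn_kxk))
  y2 <- ref_bn(ref_conv2d(x, dbb$w_1x1, pad = 0), bnspec(dbb$bn_1x1))
  pad_with <- function(z, val) {
    d <- dim(z)
    out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
    for (c in seq_len(d[3])) out[, , c, ] <- val[c]
    out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- z
    out
  }
  bias_of <- function(bn) bn$beta - bn$r_mean * bn$gamma / sqrt(bn$r_var + bn$eps)
  z <- ref_bn(ref_conv2d(x, dbb$w_seq1, pad = 0), bnspec(dbb$bn_seq1))
  y3 <- ref_bn(ref_conv2d(pad_with(z, bias_of(dbb$bn_seq1)), dbb$w_seq2, pad = 0),
               bnspec(dbb$bn_seq2))
  a <- ref_bn(ref_conv2d(x, dbb$w_avg1, pad = 0), bnspec(dbb$bn_avg1))
  ap <- pad_with(a, bias_of(dbb$bn_avg1))
  pooled <- ref_conv2d(ap, avgpool_as_conv(K, dbb$out_ch)$weights, pad = 0)
  y4 <- ref_bn(pooled, bnspec(dbb$bn_avg2))
  y1 + y2 + y3 + y4
}

# literal per-sample elastic/angular margin loss via angles (the oracle for
# eml_loss); margin applied through acos/cos directly
ref_margin_loss <- function(e, labels, w, s, m) {
  en <- e / sqrt(rowSums(e^2))
  wn <- w / sqrt(rowSums(w^2))
  total <- 0
  for (i in seq_len(nrow(e))) {
    cosv <- as.vector(wn %*% en[i, ])
    th <- acos(pmin(pmax(cosv[labels[i]], -1), 1))
    logits <- s * cosv
    logits[labels[i]] <- s * cos(th + m)
    total <- total - (logits[labels[i]] - log(sum(exp(logits))))
  }
  total / nrow(e)
}
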