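# Coordinate attention (CoAM): spatial information is compressed by average
# pooling along each axis separately, the two direction vectors are encoded
# by a shared 1x1 convolution (+ BN + hard-swish), split back, transformed by
# independent per-axis 1x1 convolutions, squashed to (0,1) by a sigmoid, and
# multiplied back onto the input map. Each gate entry flags whether the
# corresponding row (or column) carries signal, which localizes curvilinear
# vein structures well.

#' CoAM configuration
#'
#' @param channels input/output channel count.
#' @param reduction channel reduction ratio of the shared encoder.
#' @param min_mid floor on the encoder width: `mid = max(min_mid,
#'   channels %/% reduction)`.
#' @return an object of class `coam_config`.
#' @export
coam_config <- function(channels, reduction = 32L, min_mid = 8L) {
  stopifnot(channels >= 1, reduction >= 1, min_mid >= 1)
  structure(list(channels = as.integer(channels),
                 reduction = as.integer(reduction),
                 min_mid = as.integer(min_mid)),
            class = "coam_config")
}

#' Directional average pooling
#'
#' @param x feature map, array `c(H, W, C, N)` (a matrix is promoted to
#'   `c(H, W, 1, 1)`).
#' @return list with `z_h` (array `c(H, C, N)`: per-row means) and `z_w`
#'   (array `c(W, C, N)`: per-column means).
#' @export
directional_pool <- function(x) {
  x <- as_feature_map(x)
  cpp_dir_pool(x, dim(x))
}

#' Create a coordinate-attention module
#'
#' @param cfg a [coam_config()].
#' @return a CoAM module holding the shared-encoder and per-axis gate
#'   parameters; apply it with [coam_forward()].
#' @export
coam_init <- function(cfg) {
  ly_coam(cfg$channels, cfg$reduction, cfg$min_mid)
}

#' Apply coordinate attention to a feature map
#'
#' `y[h,w,c,n] = x[h,w,c,n] * g_h[h,c,n] * g_w[w,c,n]` with both gates in
#' (0, 1); output shape equals input shape.
#'
#' @param x feature map, array `c(H, W, C, N)`.
#' @param coam a module from [coam_init()].
#' @return gated feature map of the same shape, with attribute `gates`
#'   (list of `g_h`, `g_w`).
#' @export
coam_forward <- function(x, coam) {
  x <- as_feature_map(x)
  if (dim(x)[3] != coam$channels)
    stop("coam_forward: input has ", dim(x)[3], " channels, module expects ",
         coam$channels)
  y <- fwd(coam, x, training = FALSE)
  structure(y, gates = coam$cache_gates)
}
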