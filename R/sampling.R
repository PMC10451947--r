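# Adaptive polyphase sampling (APS): shift-robust 2x spatial downsampling.
# A feature map is split into its four polyphase components x[i::2, j::2],
# (i, j) in {0,1}^2; the component with the largest Lp norm is kept. Under a
# circular shift of the input the winning component shifts with it, so the
# set of retained values is stable where plain strided subsampling is not.

#' APS configuration
#'
#' @param p norm order (> 0); the network uses `p = 2`.
#' @param pad_mode `"zero"` or `"reflect"`: how odd spatial extents are
#'   padded (bottom/right) to even before decomposition.
#' @return an object of class `aps_config`.
#' @export
aps_config <- function(p = 2, pad_mode = c("zero", "reflect")) {
  stopifnot(p > 0)
  structure(list(p = p, pad_mode = match.arg(pad_mode)), class = "aps_config")
}

# pad bottom/right to even spatial extents
pad_even <- function(x, pad_mode = "zero") {
  d <- dim(x)
  ph <- d[1] %% 2L; pw <- d[2] %% 2L
  if (ph == 0L && pw == 0L) return(x)
  out <- array(0, c(d[1] + ph, d[2] + pw, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  if (pad_mode == "reflect") {
    if (ph == 1L) out[d[1] + 1L, seq_len(d[2]), , ] <- x[d[1], , , ]
    if (pw == 1L) out[, d[2] + 1L, , ] <- out[, d[2], , ]
  }
  out
}

# the four parity components of an even-extent map, raster order
# (0,0), (0,1), (1,0), (1,1)
decompose_phases <- function(x) {
  d <- dim(x)
  ev_h <- seq(1L, d[1], by = 2L); od_h <- seq(2L, d[1], by = 2L)
  ev_w <- seq(1L, d[2], by = 2L); od_w <- seq(2L, d[2], by = 2L)
  list(x[ev_h, ev_w, , , drop = FALSE],
       x[ev_h, od_w, , , drop = FALSE],
       x[od_h, ev_w, , , drop = FALSE],
       x[od_h, od_w, , , drop = FALSE])
}

#' Split a feature map into its four polyphase components
#'
#' @param x feature map, array `c(H, W, C, N)` (a plain `H x W` matrix is
#'   promoted). Odd extents are padded to even per `pad_mode`.
#' @param pad_mode see [aps_config()].
#' @return list of four arrays in raster order `(0,0), (0,1), (1,0), (1,1)`
#'   of phase offsets `(row, col)`; together their cells partition the
#'   (padded) input.
#' @export
polyphase_decompose <- function(x, pad_mode = "zero") {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] < 1 || d[2] < 1) stop("polyphase_decompose: empty spatial extent")
  decompose_phases(pad_even(x, pad_mode))
}

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

#' Select the maximal-norm polyphase component
#'
#' Computes the Lp norm of each component over all channels and batch items
#' jointly (one map instance) and returns the winner; ties are broken by the
#' lowest raster phase index.
#'
#' @param components list of four equal-shaped arrays from
#'   [polyphase_decompose()].
#' @param cfg an [aps_config()].
#' @return list with `phase_index` (offsets `c(row, col)`), `norms`
#'   (4-vector, raster order), and `component`.
#' @export
select_phase <- function(components, cfg = aps_config()) {
  stopifnot(length(components) == 4L)
  if (any(vapply(components, anyNA, logical(1))))
    stop("select_phase: NaN in component")
  norms <- vapply(components,
                  function(z) sum(abs(z)^cfg$p)^(1 / cfg$p), numeric(1))
  i <- which.max(norms)  # first maximum = lowest raster index
  offs <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  list(phase_index = offs[[i]], norms = norms, component = components[[i]])
}

#' Shift-robust 2x downsampling by adaptive polyphase sampling
#'
#' @param x feature map (array `c(H, W, C, N)` or matrix).
#' @param cfg an [aps_config()].
#' @param max_pool if `TRUE`, apply stride-1 max pooling (window 2, same
#'   size) before decomposition — the drop-in replacement for a strided
#'   2x2 max-pool layer. Default `FALSE` (replacement for strided
#'   convolution/subsampling).
#' @return the selected component, spatial size `ceil(H/2) x ceil(W/2)`,
#'   with attributes `phase_index` and `norms`.
#' @export
aps_downsample <- function(x, cfg = aps_config(), max_pool = FALSE) {
  x <- as_feature_map(x)
  if (max_pool) x <- maxpool_s1(x)
  sel <- select_phase(polyphase_decompose(x, cfg$pad_mode), cfg)
  structure(sel$component, phase_index = sel$phase_index, norms = sel$norms)
}

# stride-1 max pooling, window 2, output size preserved (window clipped at
# the bottom/right edge)
maxpool_s1 <- function(x) {
  d <- dim(x)
  r2 <- if (d[1] > 1L) c(seq(2L, d[1]), d[1]) else 1L  # clip at edge
  c2 <- if (d[2] > 1L) c(seq(2L, d[2]), d[2]) else 1L
  pmax(x,
       x[r2, , , , drop = FALSE],
       x[, c2, , , drop = FALSE],
       x[r2, c2, , , drop = FALSE])
}
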