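# The ILCNN backbone: an input flow (3x3 DBB -> ReLU -> CoAM -> APS) taking
# 112x112x3 to 56x56x16, a middle flow of four diverse branch residual
# blocks (DBRB) taking 56x56x16 to 4x4x256 along the spatial trajectory
# 56 -> 28 -> 14 -> 7 -> 4 (the last APS zero-pads 7 -> 8), and an output
# flow (global average pooling -> 256-d vector -> dropout -> classifier
# head). Every 3x3 convolution is a DBB during training and fuses into a
# plain convolution for deployment.

#' ILCNN model configuration
#'
#' @param num_classes number of identity classes of the classifier head.
#' @param input_size input spatial side (square), default 112.
#' @param in_channels input channels (grayscale ROIs replicated to 3).
#' @param stage_channels widths: input-flow output followed by the four DBRB
#'   outputs; the last entry is the embedding dimension source.
#' @param embedding_dim pooled feature length (must equal the last stage
#'   width).
#' @param dropout_rate dropout before the output layer, in `[0, 1)`.
#' @param block `"dbrb"` (full model) or `"basic"` (plain residual ablation
#'   variant: no DBB, no CoAM, max-pool downsampling instead of APS).
#' @param head `"cosine"` (scaled-cosine classifier for the elastic-margin
#'   loss) or `"linear"` (plain fully connected + softmax baseline).
#' @param s logit scale of the cosine head.
#' @param aps_p norm order for APS phase selection.
#' @param coam_reduction,coam_min_mid coordinate-attention encoder sizing.
#' @return an object of class `ilcnn_config`.
#' @export
ilcnn_config <- function(num_classes,
                         input_size = 112L,
                         in_channels = 3L,
                         stage_channels = c(16L, 32L, 64L, 128L, 256L),
                         embedding_dim = 256L,
                         dropout_rate = 0.2,
                         block = c("dbrb", "basic"),
                         head = c("cosine", "linear"),
                         s = 64,
                         aps_p = 2,
                         coam_reduction = 32L,
                         coam_min_mid = 8L) {
  block <- match.arg(block); head <- match.arg(head)
  stopifnot(num_classes >= 1, input_size >= 16,
            length(stage_channels) == 5L,
            dropout_rate >= 0, dropout_rate < 1)
  if (stage_channels[5] != embedding_dim)
    stop("last stage width must equal embedding_dim")
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 stage_channels = as.integer(stage_channels),
                 n_blocks = 4L,
                 embedding_dim = as.integer(embedding_dim),
                 dropout_rate = dropout_rate,
                 block = block, head = head, s = s, aps_p = aps_p,
                 coam_reduction = as.integer(coam_reduction),
                 coam_min_mid = as.integer(coam_min_mid)),
            class = "ilcnn_config")
}

## ---- DBRB ------------------------------------------------------------------

# main path: DBB(3x3) -> ReLU -> DBB(3x3) -> CoAM -> APS
# shortcut:  1x1 conv -> APS (same phase as the main path, so the two grids
#            stay aligned and the residual sum keeps shift equivariance)
# merge:     add -> ReLU
ly_dbrb <- function(in_ch, out_ch, cfg) {
  m <- new_module("ly_dbrb",
                  sublayers = c("conv1", "relu1", "conv2", "coam",
                                "aps_main", "sc", "aps_sc", "relu_out"))
  m$in_ch <- in_ch; m$out_ch <- out_ch
  m$conv1 <- ly_dbb(in_ch, out_ch, 3L)
  m$relu1 <- ly_relu()
  m$conv2 <- ly_dbb(out_ch, out_ch, 3L)
  m$coam <- ly_coam(out_ch, cfg$coam_reduction, cfg$coam_min_mid)
  m$aps_main <- ly_aps(cfg$aps_p)
  m$sc <- ly_conv(in_ch, out_ch, 1L, pad = 0L, bias = TRUE)
  m$aps_sc <- ly_aps(cfg$aps_p)
  m$relu_out <- ly_relu()
  m
}

#' @export
fwd.ly_dbrb <- function(m, x, training = FALSE, ...) {
  h <- fwd(m$conv1, x, training)
  h <- fwd(m$relu1, h, training)
  h <- fwd(m$conv2, h, training)
  h <- fwd(m$coam, h, training)
  h <- fwd(m$aps_main, h, training)
  s <- fwd(m$sc, x, training)
  s <- fwd(m$aps_sc, s, training, phase = aps_phase(m$aps_main))
  fwd(m$relu_out, h + s, training)
}

#' @export
bwd.ly_dbrb <- function(m, gy, ...) {
  g <- bwd(m$relu_out, gy)
  gs <- bwd(m$aps_sc, g)
  gx <- bwd(m$sc, gs)
  gh <- bwd(m$aps_main, g)
  gh <- bwd(m$coam, gh)
  gh <- bwd(m$conv2, gh)
  gh <- bwd(m$relu1, gh)
  gx + bwd(m$conv1, gh)
}

# plain-residual ablation block (no DBB, no CoAM; 2x2 max-pool downsampling)
ly_basic_block <- function(in_ch, out_ch) {
  m <- new_module("ly_basic_block",
                  sublayers = c("conv1", "bn1", "relu1", "conv2", "bn2",
                                "pool_main", "sc", "bn_sc", "pool_sc",
                                "relu_out"))
  m$in_ch <- in_ch; m$out_ch <- out_ch
  m$conv1 <- ly_conv(in_ch, out_ch, 3L, bias = FALSE)
  m$bn1 <- ly_bn(out_ch)
  m$relu1 <- ly_relu()
  m$conv2 <- ly_conv(out_ch, out_ch, 3L, bias = FALSE)
  m$bn2 <- ly_bn(out_ch)
  m$pool_main <- ly_maxpool2()
  m$sc <- ly_conv(in_ch, out_ch, 1L, pad = 0L, bias = FALSE)
  m$bn_sc <- ly_bn(out_ch)
  m$pool_sc <- ly_maxpool2()
  m$relu_out <- ly_relu()
  m
}

#' @export
fwd.ly_basic_block <- function(m, x, training = FALSE, ...) {
  h <- fwd(m$bn1, fwd(m$conv1, x, training), training)
  h <- fwd(m$relu1, h, training)
  h <- fwd(m$bn2, fwd(m$conv2, h, training), training)
  h <- fwd(m$pool_main, h, training)
  s <- fwd(m$bn_sc, fwd(m$sc, x, training), training)
  s <- fwd(m$pool_sc, s, training)
  fwd(m$relu_out, h + s, training)
}

#' @export
bwd.ly_basic_block <- function(m, gy, ...) {
  g <- bwd(m$relu_out, gy)
  gs <- bwd(m$pool_sc, g)
  gx <- bwd(m$sc, bwd(m$bn_sc, gs))
  gh <- bwd(m$pool_main, g)
  gh <- bwd(m$conv2, bwd(m$bn2, gh))
  gh <- bwd(m$relu1, gh)
  gx + bwd(m$conv1, bwd(m$bn1, gh))
}

## ---- whole model -----------------------------------------------------------

#' Build an ILCNN model
#'
#' @param cfg an [ilcnn_config()].
#' @param mode `"train_structure"` (DBB multi-branch convolutions) or
#'   `"deploy"` (single fused convolutions; normally obtained via
#'   [reparameterize_model()] rather than built fresh).
#' @return a model object (class `ilcnn`).
#' @export
build_ilcnn <- function(cfg, mode = "train_structure") {
  stopifnot(inherits(cfg, "ilcnn_config"))
  m <- new_module("ilcnn")
  sc <- cfg$stage_channels
  basic <- cfg$block == "basic"
  m$cfg <- cfg
  m$mode <- mode
  subl <- character(0)
  if (basic) {
    m$in_conv <- ly_conv(cfg$in_channels, sc[1], 3L, bias = FALSE)
    m$in_bn <- ly_bn(sc[1])
    m$in_relu <- ly_relu()
    m$in_ds <- ly_maxpool2()
    subl <- c(subl, "in_conv", "in_bn", "in_relu", "in_ds")
  } else {
    m$in_conv <- ly_dbb(cfg$in_channels, sc[1], 3L)
    m$in_relu <- ly_relu()
    m$in_coam <- ly_coam(sc[1], cfg$coam_reduction, cfg$coam_min_mid)
    m$in_ds <- ly_aps(cfg$aps_p)
    subl <- c(subl, "in_conv", "in_relu", "in_coam", "in_ds")
  }
  for (i in 1:4) {
    blk <- if (basic) ly_basic_block(sc[i], sc[i + 1])
           else ly_dbrb(sc[i], sc[i + 1], cfg)
    m[[paste0("b", i)]] <- blk
    subl <- c(subl, paste0("b", i))
  }
  m$gap <- ly_gap()
  m$dropout <- ly_dropout(cfg$dropout_rate)
  m$head <- if (cfg$head == "cosine")
    ly_head_cosine(cfg$num_classes, cfg$embedding_dim, cfg$s)
  else ly_head_linear(cfg$num_classes, cfg$embedding_dim)
  subl <- c(subl, "gap", "dropout", "head")
  m$sublayers <- subl
  m
}

#' Forward pass through an ILCNN model
#'
#' @param model an `ilcnn` model.
#' @param x input batch, array `c(H, W, 3, N)` with `H = W =` the configured
#'   input size, values in `[0, 1]`.
#' @param training use batch statistics / dropout (training structure only).
#' @return list with `embedding` (`d x N`, unit columns), `logits`
#'   (`n x N`), `prob` (softmax of logits), and `cos` (cosine head only).
#'   Shapes of the input-flow and middle-flow outputs are recorded in
#'   `model$trace`.
#' @export
ilcnn_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  d <- dim(x)
  if (length(d) != 4L || d[1] != cfg$input_size || d[2] != cfg$input_size ||
      d[3] != cfg$in_channels)
    stop("ilcnn_forward: expected ", cfg$input_size, "x", cfg$input_size,
         "x", cfg$in_channels, " input, got ", paste(d, collapse = "x"))
  h <- fwd(model$in_conv, x, training)
  if (model$cfg$block == "basic") h <- fwd(model$in_bn, h, training)
  h <- fwd(model$in_relu, h, training)
  if (model$cfg$block == "dbrb") h <- fwd(model$in_coam, h, training)
  h <- fwd(model$in_ds, h, training)
  trace <- list(input_flow_dim = dim(h)[1:3])
  for (i in 1:4) h <- fwd(model[[paste0("b", i)]], h, training)
  trace$middle_flow_dim <- dim(h)[1:3]
  v <- fwd(model$gap, h, training)          # d x N
  trace$pooled_len <- nrow(v)
  v <- fwd(model$dropout, v, training)
  out <- fwd(model$head, v, training)
  model$trace <- trace
  prob <- apply(out$logits, 2, function(l) { e <- exp(l - max(l)); e / sum(e) })
  if (is.null(dim(prob))) prob <- matrix(prob, ncol = ncol(out$logits))
  list(embedding = out$embedding, cos = out$cos, logits = out$logits,
       prob = prob)
}

# backward entry point used by the training loop: gback is dL/dcos for the
# cosine head or dL/dlogits for the linear head
ilcnn_backward <- function(model, gback) {
  g <- bwd(model$head, gback)
  g <- bwd(model$dropout, g)
  g <- bwd(model$gap, g)
  for (i in 4:1) g <- bwd(model[[paste0("b", i)]], g)
  g <- bwd(model$in_ds, g)
  if (model$cfg$block == "dbrb") g <- bwd(model$in_coam, g)
  g <- bwd(model$in_relu, g)
  if (model$cfg$block == "basic") g <- bwd(model$in_bn, g)
  bwd(model$in_conv, g)
}

#' Fuse a trained model into its deployment structure
#'
#' Every diverse branch block is collapsed into a single 3x3 convolution
#' with bias via [reparameterize_dbb()] (using running batch-norm
#' statistics); all other layers are carried over. The returned model's
#' forward pass is equivalent to the training structure's evaluation-mode
#' forward up to floating-point rounding.
#'
#' @param model an `ilcnn` model in `"train_structure"` mode.
#' @return an `ilcnn` model in `"deploy"` mode.
#' @export
reparameterize_model <- function(model) {
  if (model$mode == "deploy")
    stop("model is already fused (deploy mode)")
  if (model$cfg$block != "dbrb")
    stop("only the DBRB variant has a fused deployment structure")
  dep <- with_preserved_rng(build_ilcnn(model$cfg, mode = "deploy"))
  dep$in_conv <- conv_from_fused(reparameterize_dbb(model$in_conv))
  dep$in_coam <- clone_module(model$in_coam)
  for (i in 1:4) {
    b <- model[[paste0("b", i)]]
    nb <- dep[[paste0("b", i)]]
    nb$conv1 <- conv_from_fused(reparameterize_dbb(b$conv1))
    nb$conv2 <- conv_from_fused(reparameterize_dbb(b$conv2))
    nb$coam <- clone_module(b$coam)
    nb$sc <- clone_module(b$sc)
  }
  dep$head <- clone_module(model$head)
  dep
}

# run an expression without disturbing the caller's RNG stream (layer
# construction draws random initial weights that fused copies discard)
with_preserved_rng <- function(expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed)
    assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  expr
}

# deep-copy a module environment (parameters and running stats, not caches)
clone_module <- function(m) {
  out <- new_module(class(m)[1], m$trainable, m$sublayers)
  for (nm in ls(m)) {
    if (startsWith(nm, "cache_") || startsWith(nm, "g_")) next
    if (nm %in% m$sublayers) out[[nm]] <- clone_module(m[[nm]])
    else out[[nm]] <- m[[nm]]
  }
  class(out) <- class(m)
  out
}

#' Count trainable parameters
#'
#' @param model an `ilcnn` model (any mode).
#' @param include_head include the dataset-dependent classifier head?
#' @return integer scalar.
#' @export
count_parameters <- function(model, include_head = FALSE) {
  total <- sum(vapply(all_params(model), function(r)
    as.numeric(length(r$env[[r$name]])), numeric(1)))
  if (!include_head)
    total <- total - sum(vapply(all_params(model$head), function(r)
      as.numeric(length(r$env[[r$name]])), numeric(1)))
  as.integer(total)
}

#' Profile a deployed model: parameters and multiply-accumulates
#'
#' Convolution cost convention: `K^2 * Cin * Cout * Hout * Wout` MACs; 1x1
#' attention convolutions and (optionally) the linear head are counted the
#' same way. Only defined for the fused deployment structure, whose costs
#' are what an embedded target would pay.
#'
#' @param model an `ilcnn` model in `"deploy"` mode.
#' @param input_size input side length (default: the configured size).
#' @param include_head include the classifier head (class-count-dependent)?
#' @return list with `param_count`, `mac_count`, `params_millions`,
#'   `gmacs` (the latter two rounded to two decimals), plus
#'   `param_count_with_head` / `mac_count_with_head`.
#' @export
profile_model <- function(model, input_size = NULL, include_head = FALSE) {
  if (model$mode != "deploy")
    stop("profile_model: fuse the model first (reparameterize_model)")
  cfg <- model$cfg
  if (is.null(input_size)) input_size <- cfg$input_size
  sc <- cfg$stage_channels
  params <- 0; macs <- 0
  conv_cost <- function(k, cin, cout, hout, wout, bias = TRUE) {
    params <<- params + k * k * cin * cout + if (bias) cout else 0
    macs <<- macs + k * k * cin * cout * hout * wout
  }
  coam_cost <- function(ch, h, w) {
    mid <- max(cfg$coam_min_mid, ch %/% cfg$coam_reduction)
    params <<- params + ch * mid + mid      # shared encoder conv
    params <<- params + 2 * mid             # encoder BN (gamma, beta)
    params <<- params + 2 * (mid * ch + ch) # per-axis gate convs
    macs <<- macs + mid * ch * (h + w)      # encoder over concat vector
    macs <<- macs + ch * mid * h + ch * mid * w
  }
  s <- input_size
  conv_cost(3, cfg$in_channels, sc[1], s, s)
  coam_cost(sc[1], s, s)
  s <- ceiling(s / 2)
  for (i in 1:4) {
    conv_cost(3, sc[i], sc[i + 1], s, s)
    conv_cost(3, sc[i + 1], sc[i + 1], s, s)
    conv_cost(1, sc[i], sc[i + 1], s, s)  # shortcut
    coam_cost(sc[i + 1], s, s)
    s <- ceiling(s / 2)
  }
  head_params <- cfg$num_classes * cfg$embedding_dim +
    if (cfg$head == "linear") cfg$num_classes else 0
  head_macs <- cfg$num_classes * cfg$embedding_dim
  out <- list(param_count = params, mac_count = macs,
              params_millions = round(params / 1e6, 2),
              gmacs = round(macs / 1e9, 2),
              param_count_with_head = params + head_params,
              mac_count_with_head = macs + head_macs)
  if (include_head) {
    out$param_count <- out$param_count_with_head
    out$mac_count <- out$mac_count_with_head
    out$params_millions <- round(out$param_count / 1e6, 2)
    out$gmacs <- round(out$mac_count / 1e9, 2)
  }
  class(out) <- "ilcnn_profile"
  out
}

#' @export
print.ilcnn_profile <- function(x, ...) {
  cat(sprintf("ILCNN profile: %.2f M params, %.2f GMACs (backbone)\n",
              x$params_millions, x$gmacs))
  cat(sprintf("  with classifier head: %d params, %d MACs\n",
              x$param_count_with_head, x$mac_count_with_head))
  invisible(x)
}

## ---- checkpoints -----------------------------------------------------------

# flatten every parameter and buffer into a plain list (checkpoint payload)
module_state <- function(m) {
  st <- list()
  for (nm in ls(m)) {
    if (startsWith(nm, "cache_") || startsWith(nm, "g_")) next
    if (nm %in% c("trainable", "sublayers", "cfg", "mode", "trace")) next
    if (nm %in% m$sublayers) st[[nm]] <- module_state(m[[nm]])
    else st[[nm]] <- m[[nm]]
  }
  st
}

set_module_state <- function(m, st) {
  for (nm in names(st)) {
    if (nm %in% m$sublayers) set_module_state(m[[nm]], st[[nm]])
    else m[[nm]] <- st[[nm]]
  }
  invisible(m)
}

#' Save / load an ILCNN checkpoint
#'
#' The checkpoint stores the configuration, the structural mode
#' (train-structure or deploy, i.e. whether the weights are fused), and all
#' parameters and running statistics.
#'
#' @param model an `ilcnn` model.
#' @param path file path.
#' @return `save_ilcnn` returns `path` invisibly; `load_ilcnn` returns the
#'   rebuilt model.
#' @export
save_ilcnn <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg), mode = model$mode,
               state = module_state(model),
               package_version = as.character(utils::packageVersion("ilcnn"))),
          path)
  invisible(path)
}

#' @rdname save_ilcnn
#' @export
load_ilcnn <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(ilcnn_config, ck$cfg[setdiff(names(ck$cfg), "n_blocks")])
  model <- with_preserved_rng(build_ilcnn(cfg, mode = ck$mode))
  if (ck$mode == "deploy") {
    # rebuild fused conv layers so fields exist before state is written
    model$in_conv <- ly_conv(cfg$in_channels, cfg$stage_channels[1], 3L)
    for (i in 1:4) {
      b <- model[[paste0("b", i)]]
      b$conv1 <- ly_conv(cfg$stage_channels[i], cfg$stage_channels[i + 1], 3L)
      b$conv2 <- ly_conv(cfg$stage_channels[i + 1], cfg$stage_channels[i + 1], 3L)
    }
  }
  set_module_state(model, ck$state)
  model
}
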