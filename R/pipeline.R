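# Training loop (AdamW + elastic-margin loss), identification evaluation by
# correct identification rate (CIR), and the ablation driver.

#' Training configuration
#'
#' @param num_classes identity classes in the dataset.
#' @param epochs training epochs (>= 1). The reference full-scale protocol
#'   uses 500; the desk-scale default is 30.
#' @param batch_size minibatch size.
#' @param learning_rate initial AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param image_size network input side length.
#' @param seed seed for all randomness (init, shuffling, dropout, margins).
#' @param eml an [eml_config()]; its `n` must equal `num_classes`.
#' @param model an [ilcnn_config()]; defaults to the standard architecture.
#' @param checkpoint_path optional path for the best-validation checkpoint.
#' @return an object of class `train_config`.
#' @export
train_config <- function(num_classes,
                         epochs = 30L,
                         batch_size = 32L,
                         learning_rate = 2e-4,
                         weight_decay = 0.01,
                         image_size = 112L,
                         seed = 1L,
                         eml = eml_config(n = num_classes),
                         model = ilcnn_config(num_classes,
                                              input_size = image_size),
                         checkpoint_path = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            weight_decay >= 0)
  if (eml$n != num_classes) stop("eml$n must equal num_classes")
  if (model$num_classes != num_classes)
    stop("model num_classes must equal num_classes")
  structure(list(num_classes = as.integer(num_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed),
                 eml = eml, model = model,
                 checkpoint_path = checkpoint_path),
            class = "train_config")
}

#' Read a training configuration from a YAML file
#'
#' The file holds top-level [train_config()] fields plus optional `eml:`
#' (fields of [eml_config()]) and `model:` (fields of [ilcnn_config()])
#' blocks; anything omitted takes the package default.
#'
#' @param path YAML file path.
#' @param num_classes identity classes (may also be given in the file).
#' @return a [train_config()].
#' @export
read_train_config <- function(path, num_classes = NULL) {
  y <- yaml::read_yaml(path)
  n <- num_classes %||% y$num_classes
  if (is.null(n)) stop("num_classes must be given in the file or as argument")
  eml <- do.call(eml_config, c(list(n = n), y$eml))
  model <- do.call(ilcnn_config, c(list(num_classes = n), y$model))
  top <- y[setdiff(names(y), c("eml", "model", "num_classes"))]
  do.call(train_config,
          c(list(num_classes = n, eml = eml, model = model), top))
}

#' Correct identification rate report
#'
#' The CIR is the ratio of correctly identified probes to all probes. A
#' probe counts as correct when its top-1 class matches the true identity
#' AND the predicted probability exceeds 50%; the plain top-1 accuracy is
#' reported alongside.
#'
#' @param correct_cases,total_cases non-negative integers.
#' @param top1_correct top-1 matches regardless of the probability rule.
#' @return an object of class `cir_report` with fields `correct_cases`,
#'   `total_cases`, `cir`, and `top1_accuracy`.
#' @export
cir_report <- function(correct_cases, total_cases,
                       top1_correct = correct_cases) {
  stopifnot(total_cases >= 1, correct_cases >= 0,
            correct_cases <= total_cases)
  structure(list(correct_cases = as.integer(correct_cases),
                 total_cases = as.integer(total_cases),
                 cir = correct_cases / total_cases,
                 top1_accuracy = top1_correct / total_cases),
            class = "cir_report")
}

#' @export
print.cir_report <- function(x, ...) {
  cat(sprintf("CIR %d/%d = %.4f (top-1 accuracy %.4f)\n",
              x$correct_cases, x$total_cases, x$cir, x$top1_accuracy))
  invisible(x)
}

# forward a set of images in evaluation mode, batched
predict_probs <- function(model, x, idx, batch_size = 32L) {
  n <- model$cfg$num_classes
  probs <- matrix(0, n, length(idx))
  for (start in seq(1, length(idx), by = batch_size)) {
    bi <- idx[start:min(start + batch_size - 1, length(idx))]
    out <- ilcnn_forward(model, x[, , , bi, drop = FALSE], training = FALSE)
    probs[, start:(start + length(bi) - 1)] <- out$prob
  }
  probs
}

#' Score identification probes from their class probabilities
#'
#' A probe is counted correct when its top-1 class matches the truth and
#' the predicted probability exceeds 50%.
#'
#' @param probs `n_classes x n_probes` matrix of softmax probabilities.
#' @param truth true class index per probe.
#' @return a [cir_report()].
#' @export
cir_from_probs <- function(probs, truth) {
  stopifnot(ncol(probs) == length(truth))
  top1 <- max.col(t(probs), ties.method = "first")
  pmaxv <- probs[cbind(top1, seq_along(truth))]
  top1_ok <- top1 == truth
  correct <- top1_ok & (pmaxv > 0.5)
  cir_report(sum(correct), length(truth), sum(top1_ok))
}

#' Evaluate identification performance
#'
#' @param model an `ilcnn` model (either mode).
#' @param x preprocessed image tensor `c(H, W, 3, M)`.
#' @param labels true identity per image (1-based).
#' @param idx indices of the probes to evaluate (default: all).
#' @param batch_size forward batch size.
#' @return a [cir_report()].
#' @export
evaluate_cir <- function(model, x, labels, idx = seq_along(labels),
                         batch_size = 32L) {
  if (max(labels[idx]) > model$cfg$num_classes)
    stop("evaluation labels exceed the model's class count")
  probs <- predict_probs(model, x, idx, batch_size)
  cir_from_probs(probs, labels[idx])
}

#' Train an ILCNN model
#'
#' Optimizes the training-structure model with AdamW. With the cosine head
#' the elastic-margin loss is used (one Gaussian margin draw per sample per
#' step); with the linear head, plain softmax cross-entropy. Logs per-epoch
#' training loss and validation CIR and keeps the best-validation weights.
#'
#' @param cfg a [train_config()].
#' @param x preprocessed image tensor `c(H, W, 3, M)`.
#' @param labels identity labels (1-based integer, length M).
#' @param split list with integer index vectors `train`, `val` (and
#'   optionally `test`), e.g. from [split_dataset()].
#' @param verbose print a line per epoch.
#' @return list with `model` (best-validation weights, train-structure
#'   mode), `history` (data frame: epoch, loss, val_cir, val_top1), and
#'   `best_epoch`.
#' @export
train_ilcnn <- function(cfg, x, labels, split, verbose = interactive()) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(split$train) == 0) stop("empty training split")
  # training steps use single-precision convolution arithmetic; evaluation
  # (and everything outside this function) stays double precision
  old_opt <- options(ilcnn.fast_math = TRUE)
  on.exit(options(old_opt), add = TRUE)
  set.seed(cfg$seed)
  model <- build_ilcnn(cfg$model)
  params <- all_params(model)
  opt <- adamw(params, lr = cfg$learning_rate,
               weight_decay = cfg$weight_decay)
  use_eml <- cfg$model$head == "cosine"
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_cir = numeric(0), val_top1 = numeric(0))
  best <- list(cir = -1, state = NULL, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- split$train[sample.int(length(split$train))]
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      xb <- x[, , , bi, drop = FALSE]
      yb <- labels[bi]
      out <- ilcnn_forward(model, xb, training = TRUE)
      if (use_eml) {
        margins <- sample_margin(cfg$eml$m, cfg$eml$sigma, length(bi))
        ls <- eml_from_cos(out$cos, yb, cfg$eml$s, margins)
        gback <- ls$dcos
      } else {
        ls <- softmax_ce(out$logits, yb)
        gback <- ls$dlogit
      }
      if (!is.finite(ls$loss))
        stop("divergence: non-finite loss at epoch ", ep)
      zero_grads(params)
      ilcnn_backward(model, gback)
      adamw_step(opt)
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    val <- if (length(split$val) > 0)
      evaluate_cir(model, x, labels, split$val, cfg$batch_size)
    else cir_report(0L, 1L)
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss,
                                val_cir = val$cir,
                                val_top1 = val$top1_accuracy))
    if (val$cir >= best$cir) {
      best <- list(cir = val$cir, state = module_state(model), epoch = ep)
    }
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f  val CIR %.4f\n",
                  ep, ep_loss, val$cir))
  }
  if (!is.null(best$state)) set_module_state(model, best$state)
  clear_caches(model)
  if (!is.null(cfg$checkpoint_path)) save_ilcnn(model, cfg$checkpoint_path)
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Ablation study: basic residual vs DBRB vs DBRB + EML
#'
#' Trains the three model variants under identical budgets and seeds and
#' reports their test CIRs. The expected ordering (DBRB + EML >= DBRB >=
#' basic on the mean) is reported, not enforced.
#'
#' @param x,labels,split as in [train_ilcnn()].
#' @param num_classes identity classes.
#' @param seeds integer vector of training seeds.
#' @param epochs epochs per run.
#' @param ... further arguments passed to [train_config()].
#' @return data frame with one row per (variant, seed): variant, seed,
#'   test CIR and top-1 accuracy.
#' @export
run_ablation <- function(x, labels, split, num_classes,
                         seeds = 1L, epochs = 10L, ...) {
  variants <- list(
    basic    = list(block = "basic", head = "linear"),
    dbrb     = list(block = "dbrb", head = "linear"),
    dbrb_eml = list(block = "dbrb", head = "cosine"))
  rows <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    for (sd in seeds) {
      mcfg <- ilcnn_config(num_classes, block = v$block, head = v$head)
      tcfg <- train_config(num_classes, epochs = epochs, seed = sd,
                           model = mcfg, ...)
      fit <- train_ilcnn(tcfg, x, labels, split, verbose = FALSE)
      rep <- evaluate_cir(fit$model, x, labels, split$test)
      rows[[length(rows) + 1]] <-
        data.frame(variant = vn, seed = sd, cir = rep$cir,
                   top1 = rep$top1_accuracy)
    }
  }
  do.call(rbind, rows)
}
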