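# Elastic angular-margin softmax loss (EML) on L2-normalized embeddings and
# classifier weights. The target-class logit is s * cos(theta_y + E) with the
# margin E drawn per sample from Normal(m, sigma); non-target logits are
# s * cos(theta_j). With sigma = 0 this is exactly the additive angular
# margin (AAM / ArcFace) softmax loss.

#' Elastic-margin loss configuration
#'
#' @param n number of identity classes.
#' @param s logit scale (> 0).
#' @param m margin mean, radians, in `[0, pi)`.
#' @param sigma margin spread (>= 0); `sigma = 0` gives a fixed margin.
#' @return an object of class `eml_config`.
#' @export
eml_config <- function(n, s = 64, m = 0.5, sigma = 0.05) {
  stopifnot(n >= 1, s > 0, m >= 0, m < pi, sigma >= 0)
  structure(list(n = as.integer(n), s = s, m = m, sigma = sigma),
            class = "eml_config")
}

#' Draw elastic margins
#'
#' One independent draw from `Normal(m, sigma)` per sample per step; with
#' `sigma = 0` every draw equals `m` exactly. Uses R's RNG stream, so results
#' are reproducible under `set.seed()`.
#'
#' @param m margin mean (radians).
#' @param sigma margin standard deviation (>= 0).
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_margin <- function(m, sigma, n = 1L) {
  stopifnot(sigma >= 0)
  rnorm(n, mean = m, sd = sigma)
}

l2_normalize_rows <- function(x, what) {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("zero-norm ", what, " cannot be L2-normalized")
  x / nrm
}

# cos(theta + E) from cos(theta), computed without arccos:
# cos(t+E) = cos t cos E - sin t sin E, sin t = sqrt(1 - cos^2 t) clamped
cos_plus_margin <- function(cost, margin) {
  sint <- sqrt(pmax(1 - cost^2, 0))
  cost * cos(margin) - sint * sin(margin)
}

#' Elastic angular-margin softmax loss
#'
#' Mean over the batch of `-log softmax` of the margin-adjusted scaled
#' cosine logits. Embeddings and class weights are L2-normalized internally,
#' so rescaling either leaves the loss unchanged.
#'
#' @param embeddings `N x d` matrix, one embedding per row (any nonzero
#'   scale).
#' @param labels integer vector of length `N`, class indices in `1..n`.
#' @param weights `n x d` matrix of classifier weights, one class per row.
#' @param cfg an [eml_config()].
#' @param margins optional numeric vector of length `N` of margin draws;
#'   by default drawn via [sample_margin()] from the current RNG stream.
#' @return non-negative scalar loss.
#' @export
eml_loss <- function(embeddings, labels, weights, cfg, margins = NULL) {
  stopifnot(is.matrix(embeddings), is.matrix(weights))
  N <- nrow(embeddings)
  if (length(labels) != N) stop("labels length must match embedding rows")
  if (nrow(weights) != cfg$n) stop("weights must have cfg$n rows")
  if (any(labels < 1L) || any(labels > cfg$n))
    stop("label out of range 1..", cfg$n)
  if (is.null(margins)) margins <- sample_margin(cfg$m, cfg$sigma, N)
  e <- l2_normalize_rows(embeddings, "embedding")
  w <- l2_normalize_rows(weights, "classifier weight")
  cosm <- w %*% t(e)  # n x N
  res <- eml_from_cos(cosm, labels, cfg$s, margins, want_grad = FALSE)
  res$loss
}

# Core: loss (and optionally dL/dcos) from the cosine matrix. Numerically
# stable via max-logit subtraction.
eml_from_cos <- function(cosm, labels, s, margins, want_grad = TRUE) {
  N <- ncol(cosm)
  tgt <- cbind(labels, seq_len(N))
  ct <- cosm[tgt]
  logits <- s * cosm
  logits[tgt] <- s * cos_plus_margin(ct, margins)
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  Z <- colSums(ex)
  p <- sweep(ex, 2, Z, "/")
  loss <- -mean(log(pmax(p[tgt], .Machine$double.xmin)))
  if (!want_grad) return(list(loss = loss, prob = p))
  dlogit <- p / N
  dlogit[tgt] <- dlogit[tgt] - 1 / N
  dcos <- s * dlogit
  # target column: d/dcos of s*cos(theta+E)
  sint <- sqrt(pmax(1 - ct^2, 0))
  dtgt <- cos(margins) + sin(margins) * ct / pmax(sint, 1e-6)
  dcos[tgt] <- s * dlogit[tgt] * dtgt
  list(loss = loss, prob = p, dcos = dcos)
}

# plain softmax cross-entropy on raw logits (ablation baseline head)
softmax_ce <- function(logits, labels, want_grad = TRUE) {
  N <- ncol(logits)
  tgt <- cbind(labels, seq_len(N))
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  p <- sweep(ex, 2, colSums(ex), "/")
  loss <- -mean(log(pmax(p[tgt], .Machine$double.xmin)))
  if (!want_grad) return(list(loss = loss, prob = p))
  dlogit <- p / N
  dlogit[tgt] <- dlogit[tgt] - 1 / N
  list(loss = loss, prob = p, dlogit = dlogit)
}
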