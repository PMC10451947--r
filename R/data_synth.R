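# Synthetic near-infrared finger-vein ROI generator, ROI preprocessing and
# per-class dataset splitting. Each identity gets one fixed "skeleton" of
# smooth curvilinear dark strokes (veins absorb NIR light) on a brighter
# tissue-like background; every image re-renders that skeleton with
# session-specific brightness, a small per-image translation, and sensor
# noise — the variation modes the identification network must tolerate.

#' Synthetic vein dataset configuration
#'
#' Defaults emulate a desk-scale slice of a multi-session finger-vein ROI
#' collection following the FV-USM protocol: 100 x 300 ROIs, two capture
#' sessions with six images each (12 per finger), a handful of veins per
#' finger, and pixel-level capture nuisances.
#'
#' @param n_identities number of finger classes.
#' @param images_per_identity images per class (divisible by `n_sessions`).
#' @param n_sessions capture sessions; brightness drifts between sessions.
#' @param roi_size `c(H, W)` of the generated ROIs.
#' @param veins_range integer range of vein strokes per finger.
#' @param vein_sd_range Gaussian half-width (px) range of a vein stroke.
#' @param max_translation_px per-image uniform integer translation bound.
#' @param brightness_jitter sd of the per-session brightness factor.
#' @param noise_sd additive Gaussian sensor-noise sd.
#' @param seed RNG seed; the dataset is a pure function of this config.
#' @return an object of class `synthetic_vein_config`.
#' @export
synthetic_vein_config <- function(n_identities = 50L,
                                  images_per_identity = 12L,
                                  n_sessions = 2L,
                                  roi_size = c(100L, 300L),
                                  veins_range = c(3L, 6L),
                                  vein_sd_range = c(2, 4),
                                  max_translation_px = 6L,
                                  brightness_jitter = 0.08,
                                  noise_sd = 0.03,
                                  seed = 1L) {
  if (any(roi_size < 8)) stop("degenerate roi_size")
  if (images_per_identity %% n_sessions != 0)
    stop("images_per_identity must be divisible by n_sessions")
  stopifnot(n_identities >= 1, images_per_identity >= 1, n_sessions >= 1,
            max_translation_px >= 0, brightness_jitter >= 0, noise_sd >= 0)
  structure(list(n_identities = as.integer(n_identities),
                 images_per_identity = as.integer(images_per_identity),
                 n_sessions = as.integer(n_sessions),
                 roi_size = as.integer(roi_size),
                 veins_range = as.integer(veins_range),
                 vein_sd_range = vein_sd_range,
                 max_translation_px = as.integer(max_translation_px),
                 brightness_jitter = brightness_jitter,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_vein_config")
}

# one identity's fixed vein skeleton: background with slow illumination
# variation plus Gaussian-profile dark strokes along spline centerlines
vein_skeleton <- function(H, W, veins_range, vein_sd_range) {
  gx <- seq(0, 1, length.out = 6)
  bgc <- matrix(runif(36, -1, 1), 6, 6)
  rows <- seq(0, 1, length.out = H); cols <- seq(0, 1, length.out = W)
  bg_rows <- apply(bgc, 2, function(cl) stats::spline(gx, cl, xout = rows)$y)
  bg <- t(apply(bg_rows, 1, function(rw) stats::spline(gx, rw, xout = cols)$y))
  img <- 0.62 + 0.06 * bg / max(abs(bg), 1e-9)
  nv <- sample(seq(veins_range[1], veins_range[2]), 1)
  rr <- matrix(seq_len(H), H, W)
  for (v in seq_len(nv)) {
    ctrl_x <- seq(1, W, length.out = 7)
    y0 <- runif(1, 0.15, 0.85) * H
    ctrl_y <- y0 + cumsum(c(0, rnorm(6, 0, 0.09 * H)))
    ctrl_y <- pmin(pmax(ctrl_y, 3), H - 3)
    yc <- stats::spline(ctrl_x, ctrl_y, xout = seq_len(W))$y
    sdv <- runif(1, vein_sd_range[1], vein_sd_range[2])
    depth <- runif(1, 0.22, 0.4)
    cc <- matrix(yc, H, W, byrow = TRUE)
    img <- img - depth * exp(-(rr - cc)^2 / (2 * sdv^2))
  }
  img <- EBImage::imageData(EBImage::gblur(img, sigma = 1.2))
  pmin(pmax(img, 0.03), 0.97)
}

shift_image <- function(img, dy, dx, fill) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Generate a synthetic multi-session finger-vein dataset
#'
#' @param cfg a [synthetic_vein_config()].
#' @return a `vein_dataset`: list with `images` (list of `H x W` matrices in
#'   `[0, 1]`), `labels` (1-based identity index), `sessions`, `manifest`
#'   (data frame), and `cfg`. Fully reproducible from `cfg$seed`.
#' @export
generate_synthetic_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_vein_config"))
  set.seed(cfg$seed)
  H <- cfg$roi_size[1]; W <- cfg$roi_size[2]
  per_sess <- cfg$images_per_identity %/% cfg$n_sessions
  images <- vector("list", cfg$n_identities * cfg$images_per_identity)
  labels <- integer(length(images)); sessions <- integer(length(images))
  k <- 0L
  for (id in seq_len(cfg$n_identities)) {
    skel <- vein_skeleton(H, W, cfg$veins_range, cfg$vein_sd_range)
    for (s in seq_len(cfg$n_sessions)) {
      bright <- 1 + rnorm(1, 0, cfg$brightness_jitter)
      for (i in seq_len(per_sess)) {
        k <- k + 1L
        dy <- sample(-cfg$max_translation_px:cfg$max_translation_px, 1)
        dx <- sample(-cfg$max_translation_px:cfg$max_translation_px, 1)
        im <- shift_image(skel, dy, dx, fill = stats::median(skel))
        im <- im * bright + rnorm(H * W, 0, cfg$noise_sd)
        images[[k]] <- pmin(pmax(im, 0), 1)
        labels[k] <- id; sessions[k] <- s
      }
    }
  }
  manifest <- data.frame(index = seq_along(images), label = labels,
                         session = sessions)
  structure(list(images = images, labels = labels, sessions = sessions,
                 manifest = manifest, cfg = cfg),
            class = "vein_dataset")
}

#' @export
print.vein_dataset <- function(x, ...) {
  cat("Synthetic vein dataset:", length(x$images), "images,",
      x$cfg$n_identities, "identities,", x$cfg$n_sessions, "sessions\n")
  invisible(x)
}

#' Preprocess a vein ROI into a network input tensor
#'
#' Zero-pads the ROI symmetrically along its short axis to a square of side
#' `max(H, W)`, resizes bilinearly to `target x target`, and replicates the
#' gray channel to 3 channels.
#'
#' @param img `H x W` matrix in `[0, 1]` (or a list with a `pixels` field).
#' @param target output side length (default 112).
#' @return array `c(target, target, 3, 1)`.
#' @export
preprocess_roi <- function(img, target = 112L) {
  if (is.list(img)) img <- img$pixels
  stopifnot(is.matrix(img))
  H <- nrow(img); W <- ncol(img)
  if (H < 1 || W < 1) stop("preprocess_roi: non-positive dimensions")
  side <- max(H, W)
  sq <- matrix(0, side, side)
  r0 <- (side - H) %/% 2; c0 <- (side - W) %/% 2
  sq[r0 + seq_len(H), c0 + seq_len(W)] <- img
  rs <- if (side == target) sq
        else EBImage::imageData(EBImage::resize(sq, w = target, h = target))
  rs <- pmin(pmax(rs, 0), 1)
  array(rep(rs, 3), c(target, target, 3, 1))
}

# preprocess a whole dataset into one input tensor (target^2 x 3 x M)
preprocess_dataset <- function(ds, target = 112L) {
  M <- length(ds$images)
  x <- array(0, c(target, target, 3, M))
  for (i in seq_len(M)) x[, , , i] <- preprocess_roi(ds$images[[i]], target)
  x
}

#' Dataset split specification
#'
#' @param ratios integer `c(train, val, test)` proportions, e.g. `c(4, 1, 1)`.
#' @param seed shuffle seed.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(4L, 1L, 1L), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
  structure(list(ratios = as.integer(ratios), seed = as.integer(seed)),
            class = "split_spec")
}

#' Per-class proportional train/validation/test split
#'
#' Within each class, images are shuffled (seeded) and allocated to the
#' three sets in proportion to `spec$ratios` (largest-remainder rounding in
#' the order train, validation, test). The three sets are disjoint and
#' exhaustive.
#'
#' @param labels integer class label per image (or a `vein_dataset`).
#' @param spec a [split_spec()].
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, spec = split_spec()) {
  if (inherits(labels, "vein_dataset")) labels <- labels$labels
  r <- spec$ratios; rs <- sum(r)
  set.seed(spec$seed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n <- length(idx)
    if (n < rs)
      stop("split_dataset: class ", cl, " has ", n,
           " images, fewer than sum(ratios) = ", rs)
    idx <- idx[sample.int(n)]
    exact <- n * r / rs
    sizes <- floor(exact)
    rem <- n - sum(sizes)
    if (rem > 0) {
      order_rem <- order(exact - sizes, decreasing = TRUE)
      sizes[order_rem[seq_len(rem)]] <- sizes[order_rem[seq_len(rem)]] + 1L
    }
    ends <- cumsum(sizes)
    out$train <- c(out$train, idx[seq_len(sizes[1])])
    if (sizes[2] > 0) out$val <- c(out$val, idx[(ends[1] + 1):ends[2]])
    if (sizes[3] > 0) out$test <- c(out$test, idx[(ends[2] + 1):ends[3]])
  }
  out
}

#' Write / read a vein dataset as PNG files
#'
#' Layout: `identity_<k>/session_<s>/img_<i>.png` plus a `manifest.csv`
#' (path, label, session) at the root.
#'
#' @param ds a `vein_dataset`.
#' @param dir target directory (created if missing).
#' @return `write_vein_dataset` returns `dir` invisibly;
#'   `read_vein_dataset` returns a `vein_dataset`-shaped list.
#' @export
write_vein_dataset <- function(ds, dir) {
  paths <- character(length(ds$images))
  counters <- list()
  for (i in seq_along(ds$images)) {
    key <- paste(ds$labels[i], ds$sessions[i], sep = "_")
    counters[[key]] <- (counters[[key]] %||% 0L) + 1L
    sub <- file.path(dir, sprintf("identity_%03d", ds$labels[i]),
                     sprintf("session_%d", ds$sessions[i]))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(sub, sprintf("img_%03d.png", counters[[key]]))
    png::writePNG(ds$images[[i]], paths[i])
  }
  manifest <- data.frame(path = paths, label = ds$labels,
                         session = ds$sessions)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_vein_dataset
#' @export
read_vein_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 3L) im <- im[, , 1]
    im
  })
  structure(list(images = images, labels = manifest$label,
                 sessions = manifest$session, manifest = manifest,
                 cfg = NULL),
            class = "vein_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference acquisition protocols of the public finger-vein databases
#'
#' Class and image counts implied by the acquisition protocols the package
#' emulates: each finger is one identity class, and every finger is imaged
#' a fixed number of times per capture session.
#'
#' @return data frame with one row per database: subjects, fingers per
#'   subject, images per finger per session, sessions, and the derived
#'   `classes` and `images` totals.
#' @export
reference_protocols <- function() {
  p <- data.frame(
    database = c("FV-USM", "PLUSVein-FV3"),
    subjects = c(123L, 60L),
    fingers_per_subject = c(4L, 6L),
    images_per_finger_per_session = c(6L, 5L),
    sessions = c(2L, 1L),
    split_ratio = c("4:1:1", "3:1:1"),
    stringsAsFactors = FALSE)
  p$classes <- p$subjects * p$fingers_per_subject
  p$images <- p$classes * p$images_per_finger_per_session * p$sessions
  p
}
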