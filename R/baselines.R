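# Classical comparators: histogram-of-oriented-gradients features feeding a
# ridge-regression classifier and a C-support-vector classifier, trained on
# the balanced subset and evaluated through the same metrics path as the
# network.

#' HOG descriptor parameters
#'
#' Defaults follow the canonical pedestrian-detector configuration: 8-px
#' cells, 2x2-cell blocks, 9 unsigned orientation bins, L2-Hys block
#' normalization.
#'
#' @param cell_px Cell side in pixels; the tile side must be divisible by
#'   it.
#' @param block_cells Block side in cells (blocks slide one cell at a
#'   time).
#' @param n_orientations Number of orientation bins.
#' @param signed If `FALSE` (default) orientations live on `[0, 180)`;
#'   if `TRUE` on `[0, 360)`.
#' @return Object of class `hog_params`.
#' @export
hog_params <- function(cell_px = 8L, block_cells = 2L, n_orientations = 9L,
                       signed = FALSE) {
  stopifnot(cell_px >= 1, block_cells >= 1, n_orientations >= 2)
  structure(list(cell_px = as.integer(cell_px),
                 block_cells = as.integer(block_cells),
                 n_orientations = as.integer(n_orientations),
                 signed = isTRUE(signed)),
            class = "hog_params")
}

#' HOG descriptor length
#'
#' @param tile_px Tile side in pixels.
#' @param params A [hog_params()].
#' @return `n_blocks^2 * block_cells^2 * n_orientations` where
#'   `n_blocks = tile_px/cell_px - block_cells + 1`.
#' @export
hog_length <- function(tile_px, params = hog_params()) {
  nc <- tile_px %/% params$cell_px
  nb <- nc - params$block_cells + 1L
  if (nb < 1) stop("tile too small for the block size")
  nb * nb * params$block_cells^2 * params$n_orientations
}

#' Histogram-of-oriented-gradients features for one tile
#'
#' Luminance conversion (0.299 R + 0.587 G + 0.114 B), central-difference
#' gradients with edge replication, per-cell orientation histograms with
#' linear interpolation between adjacent bins, and L2-Hys block
#' normalization (L2-normalize, clip at 0.2, renormalize).
#'
#' @param tile A `tile` object or `tile_px x tile_px x 3` array (grayscale
#'   matrix also accepted).
#' @param params A [hog_params()].
#' @return Numeric descriptor of length [hog_length()].
#' @export
hog_features <- function(tile, params = hog_params()) {
  px <- if (inherits(tile, "tile")) tile$pixels else tile
  g <- if (is.matrix(px)) px else
    0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  n <- nrow(g)
  if (ncol(g) != n) stop("tile must be square")
  if (n %% params$cell_px != 0)
    stop("tile side ", n, " not divisible into ", params$cell_px, "-px cells")
  # central differences, edges replicated
  gx <- g[, c(2:n, n)] - g[, c(1, 1:(n - 1))]
  gy <- g[c(2:n, n), ] - g[c(1, 1:(n - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  span <- if (params$signed) 360 else 180
  ang <- (atan2(gy, gx) * 180 / pi) %% span
  nb <- params$n_orientations
  bw <- span / nb
  # linear vote between the two adjacent bins
  pos <- ang / bw - 0.5
  b0 <- floor(pos)
  w1 <- pos - b0
  b0 <- b0 %% nb
  b1 <- (b0 + 1) %% nb
  cp <- params$cell_px
  ncell <- n %/% cp
  cell_r <- (row(g) - 1) %/% cp
  cell_c <- (col(g) - 1) %/% cp
  # accumulate (cell, bin) -> magnitude
  key0 <- cell_r + ncell * cell_c + (ncell * ncell) * b0
  key1 <- cell_r + ncell * cell_c + (ncell * ncell) * b1
  hist <- numeric(ncell * ncell * nb)
  a0 <- rowsum(as.vector(mag * (1 - w1)), as.vector(key0))
  a1 <- rowsum(as.vector(mag * w1), as.vector(key1))
  hist[as.integer(rownames(a0)) + 1L] <- hist[as.integer(rownames(a0)) + 1L] + a0
  hist[as.integer(rownames(a1)) + 1L] <- hist[as.integer(rownames(a1)) + 1L] + a1
  hist <- array(hist, c(ncell, ncell, nb))
  # sliding blocks, L2-Hys
  bc <- params$block_cells
  nblk <- ncell - bc + 1L
  if (nblk < 1) stop("tile too small for the block size")
  out <- numeric(nblk * nblk * bc * bc * nb)
  k <- 0L
  blen <- bc * bc * nb
  for (bj in seq_len(nblk)) {
    for (bi in seq_len(nblk)) {
      v <- as.vector(hist[bi:(bi + bc - 1), bj:(bj + bc - 1), , drop = FALSE])
      nrm <- sqrt(sum(v^2) + 1e-10)
      v <- pmin(v / nrm, 0.2)
      v <- v / sqrt(sum(v^2) + 1e-10)
      out[(k * blen + 1):((k + 1) * blen)] <- v
      k <- k + 1L
    }
  }
  out
}

#' HOG feature matrix for a dataset
#'
#' @param dataset A `tile_dataset` (retained tiles only).
#' @param params A [hog_params()].
#' @return List with `features` (n x d matrix), `labels`, `tile_id`.
#' @export
hog_dataset <- function(dataset, params = hog_params()) {
  m <- retained_manifest(dataset)
  idx <- match(m$tile_id, dataset$manifest$tile_id)
  feats <- t(vapply(idx, function(i) hog_features(dataset$tiles[[i]], params),
                    numeric(hog_length(dim(dataset$tiles[[idx[1]]]$pixels)[1],
                                       params))))
  list(features = feats, labels = m$label, tile_id = m$tile_id)
}

#' Baseline model configuration
#'
#' @param model `"ridge"` (L2-penalized one-hot regression, penalty
#'   `alpha`) or `"c_svc"` (soft-margin SVM, penalty `C`).
#' @param alpha Ridge penalty (>= 0), default 1.
#' @param C C-SVC penalty (> 0), default 1.
#' @param kernel C-SVC kernel, `"radial"` (default, with scale-heuristic
#'   bandwidth) or `"linear"`.
#' @param seed Integer seed.
#' @return Object of class `baseline_config`.
#' @export
baseline_config <- function(model = c("ridge", "c_svc"), alpha = 1, C = 1,
                            kernel = c("radial", "linear"), seed = 1L) {
  model <- match.arg(model)
  kernel <- match.arg(kernel)
  stopifnot(alpha >= 0, C > 0)
  structure(list(model = model, alpha = alpha, C = C, kernel = kernel,
                 seed = as.integer(seed)),
            class = "baseline_config")
}

#' Fit a classical baseline classifier
#'
#' Ridge: one-hot targets regressed on centred features with L2 penalty
#' `alpha` (closed form); prediction is the argmax of the fitted scores,
#' ties going to water (the same tie rule as the network). C-SVC: e1071's
#' C-classification SVM with cost `C`; the radial kernel's bandwidth uses
#' the scale heuristic `1 / (d * mean variance)`.
#'
#' @param features n x d numeric matrix.
#' @param labels Character vector in `{"whale", "water"}` with both classes
#'   present.
#' @param config A [baseline_config()].
#' @return Object of class `baseline_model`.
#' @export
fit_baseline <- function(features, labels, config = baseline_config()) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (!all(is.finite(features))) stop("non-finite features")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  cls <- c("water", "whale")
  fit <- with_seed(config$seed, {
    if (config$model == "ridge") {
      mu <- colMeans(features)
      Xc <- sweep(features, 2, mu)
      Y <- cbind(water = as.numeric(labels == "water"),
                 whale = as.numeric(labels == "whale"))
      ym <- colMeans(Y)
      Yc <- sweep(Y, 2, ym)
      d <- ncol(Xc)
      A <- crossprod(Xc) + config$alpha * diag(d)
      b <- crossprod(Xc, Yc)
      # alpha = 0 with collinear features is rank-deficient: take the
      # minimum-norm solution
      W <- tryCatch(solve(A, b), error = function(e) MASS::ginv(A) %*% b)
      colnames(W) <- colnames(Yc)
      list(W = W, mu = mu, ym = ym)
    } else {
      gam <- 1 / (ncol(features) * max(mean(apply(features, 2, stats::var)),
                                       1e-12))
      e1071::svm(x = features, y = factor(labels, levels = cls),
                 type = "C-classification", kernel = config$kernel,
                 cost = config$C, gamma = gam, scale = FALSE)
    }
  })
  structure(list(config = config, fit = fit, classes = cls),
            class = "baseline_model")
}

#' Predict labels with a fitted baseline
#'
#' @param model A `baseline_model`.
#' @param features n x d matrix (same descriptor settings as at fit time).
#' @return Character vector of `"water"` / `"whale"` labels.
#' @export
predict_baseline <- function(model, features) {
  stopifnot(inherits(model, "baseline_model"))
  if (model$config$model == "ridge") {
    s <- sweep(features, 2, model$fit$mu) %*% model$fit$W
    s <- sweep(s, 2, model$fit$ym, "+")
    ifelse(s[, "whale"] > s[, "water"], "whale", "water")
  } else {
    as.character(stats::predict(model$fit, features))
  }
}

#' Evaluate a baseline on a labelled set
#'
#' Runs the identical water-positive confusion/metrics path as the network,
#' so baseline and CNN numbers are directly comparable.
#'
#' @param model A `baseline_model`.
#' @param features n x d matrix.
#' @param labels True labels.
#' @return A `confusion_matrix` (water positive).
#' @export
evaluate_baseline <- function(model, features, labels) {
  confusion(labels, predict_baseline(model, features),
            positive_class = "water")
}
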