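# Labeled tile datasets: class assignment under the 20%-of-whale retention
# rule, water subsampling, stratified 90/10 and k-fold splits, and the
# balanced subset used by the classical baselines.

#' Fraction of a whale instance lying inside a tile
#'
#' The denominator is the whale's total mask mass in the full scene, not the
#' tile area: "20% of the whale in the tile" is a statement about the whale.
#' Fractional-coverage masks (produced by GSD down-sampling) are summed the
#' same way.
#'
#' @param bounds List with `row0`, `col0` (0-based) and `tile_px`, the
#'   half-open pixel window `[row0, row0 + tile_px)`.
#' @param instance A `whale_instance` (or a bare mask raster).
#' @return Fraction in `[0, 1]`.
#' @export
whale_fraction <- function(bounds, instance) {
  mask <- if (inherits(instance, "whale_instance")) instance$mask else instance
  mask <- mask + 0
  tot <- sum(mask)
  if (tot <= 0) stop("empty instance mask")
  h <- nrow(mask); w <- ncol(mask)
  r <- (bounds$row0 + 1):(bounds$row0 + bounds$tile_px)
  cc <- (bounds$col0 + 1):(bounds$col0 + bounds$tile_px)
  r <- r[r >= 1 & r <= h]; cc <- cc[cc >= 1 & cc <= w]
  if (!length(r) || !length(cc)) return(0)
  sum(mask[r, cc]) / tot
}

#' Assign whale / water labels to tiles under the retention rule
#'
#' Each tile's `whale_fraction` is the maximum, over instances, of the
#' fraction of that instance lying in the tile. Tiles with fraction 0 are
#' water; tiles holding at least `retention_threshold` of some whale are
#' whale; tiles holding only a sliver (fraction in `(0, threshold)`) are
#' marked `retained = FALSE` and excluded from both classes, since such
#' slivers are recognizable only in context and the whale is better captured
#' by a neighbouring tile.
#'
#' @param tiles Output of [tile_scene()] (stride must equal tile size for
#'   fraction bookkeeping to partition each whale).
#' @param instances List of `whale_instance` from the same scene (masks on
#'   the same grid as the tiled raster).
#' @param retention_threshold Minimum retained fraction, default 0.20;
#'   the boundary is inclusive ("at least 20%").
#' @return A data frame with one row per tile: `tile_id`, `scene_id`,
#'   `row`, `col`, `whale_fraction`, `individual_id` (of the dominant
#'   instance, NA for water), `label` (`"whale"`, `"water"`, or NA when
#'   excluded), and `retained`.
#' @export
assign_labels <- function(tiles, instances, retention_threshold = 0.20) {
  if (retention_threshold <= 0 || retention_threshold > 1)
    stop("retention_threshold must lie in (0, 1]")
  grid <- attr(tiles, "grid")
  tp <- if (!is.null(grid)) grid$tile_px else dim(tiles[[1]]$pixels)[1]
  st <- if (!is.null(grid)) grid$stride_px else tp
  org <- if (!is.null(grid)) grid$origin else c(0L, 0L)
  n <- length(tiles)
  frac <- numeric(n); ind <- rep(NA_integer_, n)
  totals <- vapply(instances, function(i) sum(i$mask + 0), 0)
  if (length(instances) && any(totals <= 0)) stop("empty instance mask")
  for (i in seq_len(n)) {
    b <- list(row0 = org[1] + tiles[[i]]$grid_pos[["row"]] * st,
              col0 = org[2] + tiles[[i]]$grid_pos[["col"]] * st,
              tile_px = tp)
    if (length(instances)) {
      fr <- vapply(instances, function(wi) whale_fraction(b, wi), 0)
      k <- which.max(fr)
      frac[i] <- fr[k]
      if (fr[k] > 0) ind[i] <- instances[[k]]$individual_id
    }
  }
  label <- ifelse(frac == 0, "water",
                  ifelse(frac >= retention_threshold, "whale", NA_character_))
  data.frame(
    tile_id = paste0(vapply(tiles, function(t) t$parent_scene_id, ""), "_",
                     vapply(tiles, function(t) t$grid_pos[["row"]], 0L), "_",
                     vapply(tiles, function(t) t$grid_pos[["col"]], 0L)),
    scene_id = vapply(tiles, function(t) t$parent_scene_id, ""),
    row = vapply(tiles, function(t) t$grid_pos[["row"]], 0L),
    col = vapply(tiles, function(t) t$grid_pos[["col"]], 0L),
    whale_fraction = frac,
    individual_id = ifelse(frac == 0, NA_integer_, ind),
    label = label,
    retained = frac == 0 | frac >= retention_threshold,
    stringsAsFactors = FALSE
  )
}

#' Bundle tiles and labels into a dataset
#'
#' @param tiles List of `tile` objects (may be NULL for count-only
#'   manifests).
#' @param manifest Data frame from [assign_labels()] (or with at least
#'   `tile_id` and `label` columns). Non-retained rows are kept in the
#'   manifest but excluded from counts and from every split.
#' @return Object of class `tile_dataset` with elements `tiles`, `manifest`,
#'   `counts` (named: whale, water).
#' @export
tile_dataset <- function(tiles, manifest) {
  stopifnot(is.data.frame(manifest), "label" %in% names(manifest))
  if (!"retained" %in% names(manifest)) manifest$retained <- TRUE
  if (anyDuplicated(manifest$tile_id))
    stop("duplicate tile_id in manifest")
  kept <- manifest[manifest$retained, , drop = FALSE]
  counts <- c(whale = sum(kept$label == "whale", na.rm = TRUE),
              water = sum(kept$label == "water", na.rm = TRUE))
  structure(list(tiles = tiles, manifest = manifest, counts = counts),
            class = "tile_dataset")
}

#' @export
print.tile_dataset <- function(x, ...) {
  cat(sprintf("<tile_dataset: %d whale, %d water (%d retained of %d tiles)>\n",
              x$counts[["whale"]], x$counts[["water"]],
              sum(x$manifest$retained), nrow(x$manifest)))
  invisible(x)
}

#' Dataset class counts
#'
#' @param dataset A `tile_dataset` (or manifest data frame).
#' @return Named vector `c(whale, water, total)` over retained tiles.
#' @export
dataset_counts <- function(dataset) {
  if (is.data.frame(dataset)) dataset <- tile_dataset(NULL, dataset)
  c(dataset$counts, total = sum(dataset$counts))
}

retained_manifest <- function(dataset) {
  m <- dataset$manifest
  m[m$retained & !is.na(m$label), , drop = FALSE]
}

subset_dataset <- function(dataset, tile_ids) {
  keep <- dataset$manifest$tile_id %in% tile_ids
  m <- dataset$manifest[keep, , drop = FALSE]
  t <- if (is.null(dataset$tiles)) NULL else dataset$tiles[keep]
  tile_dataset(t, m)
}

#' Randomly subsample one class of a dataset
#'
#' Uniform sampling without replacement within the given class, leaving the
#' other class untouched (the step that reduces a 40k-tile water test pool
#' to a manageable n = 1,390 subset). Deterministic for a given seed.
#'
#' @param dataset A `tile_dataset`.
#' @param label `"water"` or `"whale"`.
#' @param n Number of tiles to keep in that class; must not exceed the class
#'   size.
#' @param seed Integer seed.
#' @return A `tile_dataset`.
#' @export
subsample_class <- function(dataset, label, n, seed = 1L) {
  stopifnot(inherits(dataset, "tile_dataset"), label %in% c("water", "whale"))
  m <- retained_manifest(dataset)
  in_class <- m$tile_id[m$label == label]
  if (n > length(in_class))
    stop("requested ", n, " tiles but class '", label, "' has only ",
         length(in_class))
  keep_class <- with_seed(seed, sample(in_class, n))
  subset_dataset(dataset, c(keep_class, m$tile_id[m$label != label]))
}

#' Stratified k-fold assignments
#'
#' Splits the retained tiles into `n_folds` folds stratified by class, so
#' each fold's test share is ~1/n_folds of each class (counts differ by at
#' most 1 across folds within a class). With 10 folds this is the rotating
#' 90% train / 10% test design. `unit = "individual"` additionally keeps all
#' duplicate frames of one whale in a single fold (preventing the same
#' individual from appearing in both train and test); `unit = "frame"`
#' (default) splits frames freely.
#'
#' @param dataset A `tile_dataset` whose manifest has an `individual_id`
#'   column when `unit = "individual"`.
#' @param n_folds Number of folds, >= 2; every class must have at least
#'   `n_folds` tiles.
#' @param unit `"frame"` or `"individual"`.
#' @param seed Integer seed.
#' @return Object of class `fold_spec`: list with `n_folds`, `assignments`
#'   (named integer vector, tile_id -> fold), `unit`, `seed`.
#' @export
make_folds <- function(dataset, n_folds = 10L, unit = c("frame", "individual"),
                       seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(inherits(dataset, "tile_dataset"), n_folds >= 2)
  m <- retained_manifest(dataset)
  cnt <- table(m$label)
  if (any(cnt < n_folds))
    stop("every class needs at least n_folds = ", n_folds,
         " tiles (have ", paste(names(cnt), cnt, sep = ": ", collapse = ", "), ")")
  assignments <- integer(0)
  with_seed(seed, {
    for (cl in c("water", "whale")) {
      ids <- m$tile_id[m$label == cl]
      if (!length(ids)) next
      if (unit == "individual" && cl == "whale") {
        grp <- m$individual_id[m$label == cl]
        grp[is.na(grp)] <- -1L
        groups <- split(ids, grp)
        groups <- groups[sample.int(length(groups))]
        sizes <- integer(n_folds)
        for (g in groups) {
          f <- which.min(sizes)
          sizes[f] <- sizes[f] + length(g)
          a <- rep(f, length(g)); names(a) <- g
          assignments <- c(assignments, a)
        }
      } else {
        ids <- sample(ids)
        a <- rep_len(seq_len(n_folds), length(ids))
        names(a) <- ids
        assignments <- c(assignments, a)
      }
    }
  })
  structure(list(n_folds = as.integer(n_folds), assignments = assignments,
                 unit = unit, seed = as.integer(seed)),
            class = "fold_spec")
}

#' Train/test split for one fold
#'
#' @param dataset A `tile_dataset`.
#' @param folds A `fold_spec` from [make_folds()].
#' @param k Fold index to hold out for testing.
#' @return List with `train` and `test` `tile_dataset`s.
#' @export
fold_split <- function(dataset, folds, k) {
  stopifnot(inherits(folds, "fold_spec"), k >= 1, k <= folds$n_folds)
  test_ids <- names(folds$assignments)[folds$assignments == k]
  train_ids <- names(folds$assignments)[folds$assignments != k]
  list(train = subset_dataset(dataset, train_ids),
       test = subset_dataset(dataset, test_ids))
}

#' Balanced subset for classical baselines
#'
#' Retains every whale tile and an equal number of uniformly sampled water
#' tiles -- the reduced training set used for the ridge and C-SVC
#' comparators, which have no batch-level imbalance correction.
#'
#' @param dataset A `tile_dataset` with water count >= whale count.
#' @param seed Integer seed.
#' @return A `tile_dataset` with a 1:1 class ratio.
#' @export
balanced_subset <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "tile_dataset"))
  nw <- dataset$counts[["whale"]]
  if (dataset$counts[["water"]] < nw)
    stop("water count (", dataset$counts[["water"]],
         ") smaller than whale count (", nw, ")")
  subsample_class(dataset, "water", nw, seed = seed)
}
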