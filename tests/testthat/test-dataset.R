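test_that("whale_fraction partitions a straddling whale across tiles", {
  # hand-made mask straddling the boundary between two 32-px tiles
  mask <- matrix(FALSE, 32, 64)
  mask[14:18, 20:45] <- TRUE                    # 5 x 26 block across the seam
  b1 <- list(row0 = 0, col0 = 0, tile_px = 32)
  b2 <- list(row0 = 0, col0 = 32, tile_px = 32)
  f1_ <- whale_fraction(b1, mask)
  f2_ <- whale_fraction(b2, mask)
  expect_equal(f1_ + f2_, 1)
  expect_equal(f1_, 5 * 13 / (5 * 26))          # cols 20..32 inside tile 1
  # fully inside / absent
  expect_equal(whale_fraction(b1, {
    m <- matrix(FALSE, 32, 64); m[5:10, 5:10] <- TRUE; m
  }), 1)
  expect_equal(whale_fraction(b2, {
    m <- matrix(FALSE, 32, 64); m[5:10, 5:10] <- TRUE; m
  }), 0)
  expect_error(whale_fraction(b1, matrix(FALSE, 32, 64)), "empty")
})

test_that("retention boundary is inclusive at the threshold", {
  # 100-pixel whale: exactly 20 pixels in the left tile, 80 in the right
  mk <- function(n_left) {
    m <- matrix(FALSE, 32, 64)
    m[11:20, (33 - n_left):32] <- n_left > 0      # 10 rows x n_left cols
    m[11:20, 33:(32 + (10 - n_left))] <- TRUE     # 10 x (10 - n_left)
    m
  }
  arr <- array(0.5, c(32, 64, 3))
  tiles <- tile_scene(arr, tile_grid(32))
  inst <- function(m) structure(list(instance_id = 0L, individual_id = 0L,
                                     mask = m, length_m = 10, pose_deg = 0),
                                class = "whale_instance")
  lab20 <- assign_labels(tiles, list(inst(mk(2))))   # 10x2 = 20 of 100 px
  expect_equal(lab20$label[lab20$col == 0], "whale")
  expect_true(all(lab20$retained))
  lab19 <- assign_labels(tiles, list(inst(mk(1))))   # 10 of 100 px -> 10% < 20%
  expect_true(is.na(lab19$label[lab19$col == 0]))
  expect_false(lab19$retained[lab19$col == 0])
  expect_equal(lab19$label[lab19$col == 1], "whale")
})

test_that("all-water scenes label every tile water with none excluded", {
  sc <- generate_scene(scene_params(96, 96, gsd_m = 0.31, seed = 8))
  tiles <- tile_scene(sc, tile_grid(32))
  lab <- assign_labels(tiles, sc$whales)
  expect_true(all(lab$label == "water"))
  expect_true(all(lab$retained))
  expect_true(all(lab$whale_fraction == 0))
})

test_that("labelling matches brute-force recomputation from masks", {
  g <- tile_grid(32)
  for (seed in 1:30) {
    sc <- generate_scene(scene_params(96, 96, gsd_m = 0.31, n_whales = 1,
                                      whale_length_m = c(12, 16),
                                      sea_state = seed %% 3, seed = seed))
    lab <- assign_labels(tile_scene(sc, g), sc$whales)
    oracle <- brute_labels(sc, g, 0.20)
    expect_equal(lab$whale_fraction, oracle$frac, tolerance = 1e-12)
    expect_identical(lab$label, oracle$label)
  }
})

test_that("labelling is invariant to tile enumeration order", {
  sc <- generate_scene(scene_params(96, 96, gsd_m = 0.31, n_whales = 1,
                                    whale_length_m = c(12, 16), seed = 17))
  tiles <- tile_scene(sc, tile_grid(32))
  lab <- assign_labels(tiles, sc$whales)
  perm <- rev(seq_along(tiles))
  shuffled <- tiles[perm]
  attr(shuffled, "grid") <- attr(tiles, "grid")
  lab2 <- assign_labels(shuffled, sc$whales)
  a <- lab[order(lab$tile_id), -1]; rownames(a) <- NULL
  b <- lab2[order(lab2$tile_id), -1]; rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("dataset counts are consistent and survey-scale totals add up", {
  aerial <- tile_dataset(NULL, make_count_manifest(690, 39726))
  expect_equal(dataset_counts(aerial),
               c(whale = 690, water = 39726, total = 40416))
  satellite <- tile_dataset(NULL, make_count_manifest(42, 40474))
  expect_equal(dataset_counts(satellite),
               c(whale = 42, water = 40474, total = 40516))
  expect_error(tile_dataset(NULL, rbind(make_count_manifest(1, 1),
                                        make_count_manifest(1, 1))),
               "duplicate")
})

test_that("subsample_class is deterministic, class-local, and bounded", {
  ds <- tile_dataset(NULL, make_count_manifest(30, 200))
  sub <- subsample_class(ds, "water", 50, seed = 5)
  expect_equal(unname(sub$counts), c(30, 50))
  sub2 <- subsample_class(ds, "water", 50, seed = 5)
  expect_identical(sort(sub$manifest$tile_id), sort(sub2$manifest$tile_id))
  sub3 <- subsample_class(ds, "water", 50, seed = 6)
  expect_false(identical(sort(sub$manifest$tile_id),
                         sort(sub3$manifest$tile_id)))
  # n = class size is the identity up to order
  all_w <- subsample_class(ds, "water", 200, seed = 1)
  expect_equal(unname(all_w$counts), c(30, 200))
  expect_error(subsample_class(ds, "water", 201, seed = 1), "only")
})

test_that("stratified folds give near-equal per-class test shares", {
  ds <- tile_dataset(NULL, make_count_manifest(230, 12306))
  folds <- make_folds(ds, n_folds = 10, seed = 3)
  m <- ds$manifest
  for (k in 1:10) {
    ids <- names(folds$assignments)[folds$assignments == k]
    nw <- sum(m$label[m$tile_id %in% ids] == "water")
    expect_true(nw %in% c(1230L, 1231L))
  }
  # folds partition the dataset
  expect_setequal(names(folds$assignments), m$tile_id)
  sp <- fold_split(ds, folds, 1)
  expect_equal(sum(sp$train$counts) + sum(sp$test$counts), nrow(m))
  expect_length(intersect(sp$train$manifest$tile_id,
                          sp$test$manifest$tile_id), 0)
})

test_that("leave-one-out folds test exactly one tile each", {
  ds <- tile_dataset(NULL, make_count_manifest(4, 4))
  folds <- make_folds(ds, n_folds = 4, seed = 1)
  for (k in 1:4)
    expect_equal(sum(folds$assignments == k), 2)  # 1 whale + 1 water
})

test_that("individual-unit folds never split one whale across folds", {
  # 5 individuals x 4 duplicate frames
  rows <- do.call(rbind, lapply(0:4, function(ind) {
    data.frame(tile_id = paste0("w", ind, "_", 1:4), scene_id = "s",
               row = 1:4, col = ind, whale_fraction = 1,
               individual_id = ind, label = "whale", retained = TRUE,
               stringsAsFactors = FALSE)
  }))
  water <- make_count_manifest(0, 40)
  ds <- tile_dataset(NULL, rbind(rows, water))
  folds <- make_folds(ds, n_folds = 5, unit = "individual", seed = 2)
  m <- ds$manifest
  for (ind in 0:4) {
    ids <- m$tile_id[!is.na(m$individual_id) & m$individual_id == ind]
    expect_length(unique(folds$assignments[ids]), 1)
  }
  expect_error(make_folds(ds, n_folds = 50, seed = 1), "at least")
})

test_that("balanced_subset yields an exact 1:1 ratio for every seed", {
  ds <- tile_dataset(NULL, make_count_manifest(25, 400))
  for (seed in 1:20) {
    bal <- balanced_subset(ds, seed = seed)
    expect_equal(unname(bal$counts), c(25, 25))
  }
  inverted <- tile_dataset(NULL, make_count_manifest(10, 5))
  expect_error(balanced_subset(inverted), "smaller")
})
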