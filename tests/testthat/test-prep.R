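test_that("bilinear down-sampling preserves constants and computes target dims", {
  sc <- generate_scene(scene_params(496, 496, gsd_m = 0.02, seed = 1))
  sc$pixels[] <- 0.5
  ds <- bilinear_downsample(sc, 0.31)
  # 496 * 0.02 / 0.31 = 32 exactly
  expect_equal(dim(ds$pixels)[1:2], c(32L, 32L))
  expect_equal(ds$gsd_m, 0.31)
  expect_true(all(abs(ds$pixels - 0.5) < 1e-12))
})

test_that("down-sampling approximately preserves the global mean", {
  for (seed in 1:20) {
    sc <- generate_scene(scene_params(128, 128, gsd_m = 0.0775,
                                      sea_state = seed %% 4, seed = seed))
    ds <- bilinear_downsample(sc, 0.31)
    expect_lt(abs(mean(ds$pixels) - mean(sc$pixels)) / mean(sc$pixels), 0.01)
  }
})

test_that("down-sampling at the current GSD is the identity; upsampling refused", {
  sc <- generate_scene(scene_params(64, 64, gsd_m = 0.31, seed = 1))
  expect_identical(bilinear_downsample(sc, 0.31), sc)
  expect_identical(bilinear_downsample(sc, 0.31 + 1e-12), sc)
  expect_error(bilinear_downsample(sc, 0.02), "finer")
})

test_that("masks survive down-sampling as area-true fractional coverage", {
  sc <- generate_scene(scene_params(512, 512, gsd_m = 0.02, n_whales = 1,
                                    whale_length_m = c(8, 8), seed = 2))
  m_fine <- sc$whales[[1]]$mask + 0
  ds <- bilinear_downsample(sc, 0.31)
  m_coarse <- ds$whales[[1]]$mask
  expect_true(all(m_coarse >= 0 & m_coarse <= 1))
  # total mask area in m^2 is conserved by area-weighted resampling
  expect_lt(abs(sum(m_fine) * 0.02^2 - sum(m_coarse) * (512 * 0.02 / 33)^2) /
              (sum(m_fine) * 0.02^2), 0.01)
})

test_that("area_downsample equals a brute-force integer block average", {
  set.seed(3)
  m <- matrix(runif(48 * 64), 48, 64)
  out <- whaletiles:::area_downsample(m, 12, 16)
  brute <- matrix(0, 12, 16)
  for (i in 1:12) for (j in 1:16)
    brute[i, j] <- mean(m[((i - 1) * 4 + 1):(i * 4), ((j - 1) * 4 + 1):(j * 4)])
  expect_equal(out, brute, tolerance = 1e-12)
})

test_that("pansharpening is exact when the pan is the upsampled simulated pan", {
  sc <- generate_scene(scene_params(96, 96, gsd_m = 0.31, n_ms_bands = 4,
                                    sea_state = 2, seed = 11))
  simpan <- apply(sc$ms, c(1, 2), mean)
  up <- simpan[rep(1:24, each = 4), rep(1:24, each = 4)]
  out <- gram_schmidt_pansharpen(sc$ms, up, method = "nearest")
  for (b in 1:4) {
    upms <- sc$ms[, , b][rep(1:24, each = 4), rep(1:24, each = 4)]
    expect_lt(max(abs(out[, , b] - upms)), 1e-6)
  }
})

test_that("degenerate substitution: identical bands equal to block-averaged pan", {
  set.seed(4)
  coarse <- matrix(runif(24 * 24, 0.2, 0.8), 24, 24)
  pan <- coarse[rep(1:24, each = 4), rep(1:24, each = 4)]  # constant 4x4 blocks
  ms <- array(rep(coarse, 3), c(24, 24, 3))
  out <- gram_schmidt_pansharpen(ms, pan, method = "nearest")
  for (b in 1:3) expect_lt(max(abs(out[, , b] - pan)), 1e-6)
})

test_that("pansharpened output block-averages back to the input bands", {
  for (seed in c(21, 22)) for (ss in c(0, 3, 5)) {
    sc <- generate_scene(scene_params(96, 96, gsd_m = 0.31, n_ms_bands = 4,
                                      sea_state = ss, seed = seed))
    ps <- gram_schmidt_pansharpen(sc$ms, sc$pan)
    back <- array(0, dim(sc$ms))
    for (b in 1:4) back[, , b] <- whaletiles:::area_downsample(ps[, , b], 24, 24)
    expect_lt(sqrt(mean((back - sc$ms)^2)), 0.02)
  }
})

test_that("pansharpening validates grids, weights, and degenerate inputs", {
  ms <- array(runif(24 * 24 * 3), c(24, 24, 3))
  expect_error(gram_schmidt_pansharpen(ms, matrix(0.5, 95, 96)), "integer multiple")
  expect_error(gram_schmidt_pansharpen(ms, matrix(runif(96 * 96), 96, 96),
                                       weights = c(1, 1)), "one per band")
  expect_error(gram_schmidt_pansharpen(ms, matrix(runif(96 * 96), 96, 96),
                                       weights = c(0, 0, 0)), "weights")
  flat <- array(0.5, c(24, 24, 3))
  expect_error(gram_schmidt_pansharpen(flat, matrix(runif(96 * 96), 96, 96)),
               "degenerate")
})

test_that("extract_rgb selects and validates bands", {
  ms <- array(seq_len(8 * 8 * 8) / (8 * 8 * 8), c(8, 8, 8))
  out <- extract_rgb(ms, c(red = 4, green = 2, blue = 1))
  expect_equal(dim(out), c(8, 8, 3))
  expect_identical(out[, , 1], ms[, , 4])
  expect_identical(out[, , 2], ms[, , 2])
  expect_identical(out[, , 3], ms[, , 1])
  rgb <- ms[, , 1:3]
  expect_identical(extract_rgb(rgb), rgb)
  expect_error(extract_rgb(ms, c(red = 9, green = 2, blue = 1)), "outside")
  expect_error(extract_rgb(ms, c(red = 1, green = 2)), "band_map")
})

test_that("tile counts and positions follow the grid closed form", {
  arr <- array(runif(64 * 96 * 3), c(64, 96, 3))
  tiles <- tile_scene(arr, tile_grid(32))
  expect_length(tiles, 6)
  pos <- t(vapply(tiles, function(t) t$grid_pos, c(row = 0L, col = 0L)))
  expect_equal(sort(unique(pos[, "row"])), 0:1)
  expect_equal(sort(unique(pos[, "col"])), 0:2)
  # trailing strips are dropped
  arr2 <- array(runif(70 * 70 * 3), c(70, 70, 3))
  expect_length(tile_scene(arr2, tile_grid(32)), 4)
  # overlapping grid
  arr3 <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_length(tile_scene(arr3, tile_grid(32, stride_px = 16)), 9)
  expect_error(tile_scene(array(0, c(20, 20, 3)), tile_grid(32)), "smaller")
})

test_that("tile count matches the sliding-window oracle on random configurations", {
  set.seed(10)
  for (i in 1:100) {
    H <- sample(32:140, 1); W <- sample(32:140, 1)
    tile <- sample(8:32, 1)
    stride <- sample(seq_len(tile), 1)
    org <- c(sample(0:3, 1), sample(0:3, 1))
    if (H < org[1] + tile || W < org[2] + tile) next
    arr <- array(0.5, c(H, W, 3))
    g <- tile_grid(tile, stride, org)
    expect_length(tile_scene(arr, g), brute_tile_count(H, W, tile, stride, org))
  }
})

test_that("disjoint tiling mosaics back to the covered raster bit-exactly", {
  arr <- array(runif(96 * 64 * 3), c(96, 64, 3))
  tiles <- tile_scene(arr, tile_grid(32))
  rec <- array(NA_real_, c(96, 64, 3))
  for (t in tiles) {
    r0 <- t$grid_pos[["row"]] * 32; c0 <- t$grid_pos[["col"]] * 32
    rec[(r0 + 1):(r0 + 32), (c0 + 1):(c0 + 32), ] <- t$pixels
  }
  expect_identical(rec, arr)
})

test_that("tile_area_m2 gives the ground footprint", {
  expect_equal(round(tile_area_m2(32, 0.31), 1), 98.4)
  expect_equal(tile_area_m2(32, 0.31), 98.4064)
  expect_equal(tile_area_m2(1, 1), 1)
  expect_equal(tile_area_m2(32, 0.02), 0.4096)
  expect_error(tile_area_m2(0, 1))
  expect_error(tile_area_m2(32, 0))
})

test_that("upscale_tile enlarges, keeps constants, and refuses shrinking", {
  const <- array(0.7, c(32, 32, 3))
  up <- upscale_tile(const, 224)
  expect_equal(dim(up), c(224, 224, 3))
  expect_true(all(abs(up - 0.7) < 1e-12))
  expect_identical(upscale_tile(const, 32), const)
  expect_error(upscale_tile(const, 16), "shrink")
  # nearest-neighbour 7x enlargement of a checkerboard is an exact kron
  checker <- array(0, c(32, 32, 3))
  checker[1:16, 1:16, ] <- 1; checker[17:32, 17:32, ] <- 1
  up2 <- upscale_tile(checker, 224, method = "nearest")
  kron <- checker[rep(1:32, each = 7), rep(1:32, each = 7), ]
  expect_equal(up2, kron)
})
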