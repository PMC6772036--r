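# Fixtures built in code: tiny labelled tile sets and hand-made scenes used
# across the suite. Everything is seeded; nothing touches disk.

# A linearly separable two-class tile set: water tiles are noisy flat fields,
# whale tiles carry a centred dark ellipse. Returns a tile_dataset.
make_blob_tileset <- function(n_whale, n_water, px = 32L, contrast = 0.3,
                              noise = 0.02, seed = 1L) {
  set.seed(seed)
  tiles <- vector("list", n_whale + n_water)
  rows <- vector("list", n_whale + n_water)
  mk_tile <- function(dark) {
    base <- 0.5 + noise * matrix(rnorm(px * px), px, px)
    if (dark) {
      cy <- px / 2 + runif(1, -3, 3); cx <- px / 2 + runif(1, -3, 3)
      th <- runif(1, 0, pi)
      u <- outer(seq_len(px) - cy, seq_len(px) - cx,
                 function(a, b) a * cos(th) + b * sin(th))
      v <- outer(seq_len(px) - cy, seq_len(px) - cx,
                 function(a, b) -a * sin(th) + b * cos(th))
      inside <- (u / (0.4 * px))^2 + (v / (0.1 * px))^2 <= 1
      base[inside] <- base[inside] - contrast
    }
    arr <- array(0, c(px, px, 3))
    for (b in 1:3) arr[, , b] <- pmin(pmax(base, 0), 1)
    arr
  }
  k <- 0L
  for (i in seq_len(n_whale + n_water)) {
    dark <- i <= n_whale
    k <- k + 1L
    tiles[[k]] <- structure(list(pixels = mk_tile(dark),
                                 grid_pos = c(row = k, col = 0L),
                                 parent_scene_id = "blob", gsd_m = 0.31),
                            class = "tile")
    rows[[k]] <- data.frame(tile_id = paste0("blob_", k, "_0"),
                            scene_id = "blob", row = k, col = 0L,
                            whale_fraction = as.numeric(dark),
                            individual_id = if (dark) k else NA_integer_,
                            label = if (dark) "whale" else "water",
                            retained = TRUE, stringsAsFactors = FALSE)
  }
  tile_dataset(tiles, do.call(rbind, rows))
}

# A count-only manifest (no pixels) with the given class sizes.
make_count_manifest <- function(n_whale, n_water) {
  n <- n_whale + n_water
  data.frame(
    tile_id = paste0("t", seq_len(n)),
    scene_id = "counts", row = seq_len(n), col = 0L,
    whale_fraction = rep(c(1, 0), c(n_whale, n_water)),
    individual_id = c(seq_len(n_whale), rep(NA_integer_, n_water)),
    label = rep(c("whale", "water"), c(n_whale, n_water)),
    retained = TRUE, stringsAsFactors = FALSE
  )
}

# Brute-force sliding-window tile count (the oracle for the closed form).
brute_tile_count <- function(H, W, tile, stride, origin = c(0L, 0L)) {
  n <- 0L
  r <- origin[1]
  while (r + tile <= H) {
    c <- origin[2]
    while (c + tile <= W) { n <- n + 1L; c <- c + stride }
    r <- r + stride
  }
  n
}

# Brute-force whale-tile labelling straight from instance masks: for each
# tile window, the fraction of each instance's pixels inside it.
brute_labels <- function(scene, grid, threshold) {
  d <- dim(scene$pixels)
  tp <- grid$tile_px; st <- grid$stride_px
  nr <- floor((d[1] - grid$origin[1] - tp) / st) + 1
  nc <- floor((d[2] - grid$origin[2] - tp) / st) + 1
  out <- NULL
  for (r in seq_len(nr) - 1L) for (cc in seq_len(nc) - 1L) {
    r0 <- grid$origin[1] + r * st; c0 <- grid$origin[2] + cc * st
    f <- 0
    for (wi in scene$whales) {
      mm <- wi$mask + 0
      f <- max(f, sum(mm[(r0 + 1):(r0 + tp), (c0 + 1):(c0 + tp)]) / sum(mm))
    }
    lab <- if (f == 0) "water" else if (f >= threshold) "whale" else NA_character_
    out <- rbind(out, data.frame(row = r, col = cc, frac = f, label = lab,
                                 stringsAsFactors = FALSE))
  }
  out
}
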