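# Raster geometry: GSD-matched resampling, Gram-Schmidt pansharpening,
# band selection, tiling, and tile enlargement.
#
# Pixel conventions throughout: 0-based grid coordinates, row-major
# enumeration, origin at the top-left, half-open tile intervals
# [r*stride, r*stride + tile_px).

# Bilinear (or nearest) resize of a matrix or H x W x C array, delegated to
# EBImage. EBImage stores x (columns) first, so arrays are transposed on the
# way in and out.
resize_raster <- function(arr, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  filt <- if (method == "bilinear") "bilinear" else "none"
  if (is.matrix(arr)) {
    img <- EBImage::Image(t(arr))
    out <- EBImage::imageData(EBImage::resize(img, w = out_w, h = out_h,
                                              filter = filt))
    return(t(out))
  }
  stopifnot(length(dim(arr)) == 3)
  img <- EBImage::Image(aperm(arr, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::imageData(EBImage::resize(img, w = out_w, h = out_h,
                                            filter = filt))
  aperm(out, c(2, 1, 3))
}

# Exact area-weighted down-sampling of a single-channel raster to an
# (out_h x out_w) grid. Each output pixel is the mean of the source image
# over its footprint rectangle, computed exactly from a summed-area table:
# the SAT of a piecewise-constant image is piecewise bilinear, so bilinear
# interpolation at fractional footprint corners is exact. Used to carry
# whale masks through GSD changes as fractional-coverage rasters.
area_downsample <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(out_h >= 1, out_w >= 1, out_h <= h, out_w <= w)
  sat <- matrix(0, h + 1, w + 1)
  cs <- m
  if (h > 1) cs <- matrix(apply(cs, 2, cumsum), h, w)   # down rows
  cs <- t(cs)
  if (w > 1) cs <- matrix(apply(cs, 2, cumsum), w, h)   # across columns
  sat[-1, -1] <- t(cs)
  sat_at <- function(ys, xs) {
    # bilinear interpolation of the SAT at real-valued (y, x), vectorized on
    # the outer grid ys x xs; coordinates in [0, h] x [0, w]
    y0 <- pmin(floor(ys), h - 1); x0 <- pmin(floor(xs), w - 1)
    fy <- ys - y0; fx <- xs - x0
    i0 <- y0 + 1L; j0 <- x0 + 1L
    A <- sat[i0, j0, drop = FALSE]; B <- sat[i0, j0 + 1L, drop = FALSE]
    C <- sat[i0 + 1L, j0, drop = FALSE]; D <- sat[i0 + 1L, j0 + 1L, drop = FALSE]
    W1 <- outer(1 - fy, 1 - fx); W2 <- outer(1 - fy, fx)
    W3 <- outer(fy, 1 - fx); W4 <- outer(fy, fx)
    A * W1 + B * W2 + C * W3 + D * W4
  }
  ry <- h / out_h; rx <- w / out_w
  y0 <- (0:(out_h - 1)) * ry; y1 <- (1:out_h) * ry
  x0 <- (0:(out_w - 1)) * rx; x1 <- (1:out_w) * rx
  ints <- sat_at(y1, x1) - sat_at(y0, x1) - sat_at(y1, x0) + sat_at(y0, x0)
  ints / (ry * rx)
}

#' Down-sample a scene to a coarser ground-sample distance
#'
#' Bilinear resampling of scene intensities to `target_gsd_m` (the operation
#' that turns ~2 cm aerial frames into satellite-resolution training
#' imagery). Output dimensions are `round(dim * src_gsd / target_gsd)`.
#' Whale masks are resampled by exact area-weighted averaging and carried
#' as fractional-coverage rasters, so the 20%-of-whale retention rule stays
#' meaningful at the coarser grid.
#'
#' Requesting the current GSD (within 1e-9) returns the scene unchanged;
#' requesting a finer GSD is an error (use [upscale_tile()] for
#' enlargement).
#'
#' @param scene A `whale_scene`.
#' @param target_gsd_m Target GSD in metres per pixel, coarser than the
#'   scene's.
#' @return A `whale_scene` at the target GSD whose whale masks are numeric
#'   fractional-coverage rasters in `[0, 1]`.
#' @export
bilinear_downsample <- function(scene, target_gsd_m) {
  stopifnot(inherits(scene, "whale_scene"), target_gsd_m > 0)
  if (abs(target_gsd_m - scene$gsd_m) <= 1e-9) return(scene)
  if (target_gsd_m < scene$gsd_m)
    stop("target GSD (", target_gsd_m, ") is finer than the scene's (",
         scene$gsd_m, "); down-sampling only -- use upscale_tile() to enlarge")
  d <- dim(scene$pixels)
  out_h <- max(1L, as.integer(round(d[1] * scene$gsd_m / target_gsd_m)))
  out_w <- max(1L, as.integer(round(d[2] * scene$gsd_m / target_gsd_m)))
  px <- resize_raster(scene$pixels, out_h, out_w, "bilinear")
  px <- pmin(pmax(px, 0), 1)
  whales <- lapply(scene$whales, function(wi) {
    wi$mask <- pmin(pmax(area_downsample(wi$mask + 0, out_h, out_w), 0), 1)
    wi
  })
  out <- scene
  out$pixels <- px
  out$whales <- whales
  out$gsd_m <- target_gsd_m
  out$ms <- NULL; out$pan <- NULL
  out
}

#' Gram-Schmidt pansharpening
#'
#' Fuses a coarse multispectral stack with a fine panchromatic band. The
#' procedure: (1) simulate a low-resolution pan band as the weighted sum of
#' the multispectral bands; (2) Gram-Schmidt-orthogonalize the band vectors
#' with the simulated pan as the first component; (3) upsample the
#' components, substitute the true pan for the simulated one after matching
#' its (block-averaged) mean and standard deviation to the simulated pan's; (4)
#' invert the transform to recover fine-resolution bands, clipped to
#' `[0, 1]`.
#'
#' @param ms H x W x B coarse multispectral array (or H x W matrix for one
#'   band).
#' @param pan Fine panchromatic matrix whose grid is an integer multiple of
#'   the multispectral grid (4x for the 124 cm / 31 cm pairing).
#' @param weights Non-negative pan-simulation weights, one per band
#'   (default uniform).
#' @param method Interpolation used to upsample the Gram-Schmidt
#'   components: `"bilinear"` (default) or `"nearest"`.
#' @return Fine-resolution B-band array with the pan's grid.
#' @export
gram_schmidt_pansharpen <- function(ms, pan, weights = NULL,
                                    method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (is.matrix(ms)) ms <- array(ms, c(dim(ms), 1L))
  stopifnot(length(dim(ms)) == 3, is.matrix(pan))
  hm <- dim(ms)[1]; wm <- dim(ms)[2]; B <- dim(ms)[3]
  hp <- nrow(pan); wp <- ncol(pan)
  if (hp %% hm != 0 || wp %% wm != 0 || hp / hm != wp / wm)
    stop("pan grid must be the same integer multiple of the multispectral grid in both directions")
  if (is.null(weights)) weights <- rep(1, B)
  if (length(weights) != B || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum, one per band")
  weights <- weights / sum(weights)

  sim_pan <- matrix(0, hm, wm)
  for (b in seq_len(B)) sim_pan <- sim_pan + weights[b] * ms[, , b]
  if (stats::sd(sim_pan) == 0)
    stop("degenerate simulated pan (zero variance); cannot orthogonalize")
  if (stats::sd(pan) == 0)
    stop("degenerate pan band (zero variance)")

  # Gram-Schmidt at the coarse scale; component 1 is the simulated pan.
  n <- hm * wm
  comps <- vector("list", B + 1L)
  means <- numeric(B)
  phi <- matrix(0, B, B + 1L)        # phi[k, j]: projection of band k on comp j
  comps[[1]] <- sim_pan - mean(sim_pan)
  for (k in seq_len(B)) {
    means[k] <- mean(ms[, , k])
    resid <- ms[, , k] - means[k]
    for (j in seq_len(k)) {
      denom <- sum(comps[[j]]^2)
      ph <- if (denom > 0) sum((ms[, , k] - means[k]) * comps[[j]]) / denom else 0
      phi[k, j] <- ph
      resid <- resid - ph * comps[[j]]
    }
    comps[[k + 1L]] <- resid
  }

  up <- function(m) resize_raster(m, hp, wp, method)
  comps_f <- lapply(comps, up)
  # Statistics-matched substitution of the true pan for component 1. The
  # match is enforced on the multispectral grid: after block-averaging back
  # to the coarse grid, the substituted pan has the simulated pan's mean and
  # standard deviation. This keeps the sharpened product spectrally
  # consistent with the input bands even when the pan carries fine detail
  # (whitecap speckle) invisible at the coarse grid.
  ba_pan <- area_downsample(pan, hm, wm)
  if (stats::sd(ba_pan) == 0)
    stop("degenerate pan band (zero variance at the multispectral grid)")
  g <- stats::sd(comps[[1]]) / stats::sd(ba_pan)
  pan_sub <- (pan - mean(ba_pan)) * g + mean(comps_f[[1]])
  comps_f[[1]] <- pan_sub

  out <- array(0, c(hp, wp, B))
  for (k in seq_len(B)) {
    band <- means[k] + comps_f[[k + 1L]]
    for (j in seq_len(k)) band <- band + phi[k, j] * comps_f[[j]]
    out[, , k] <- pmin(pmax(band, 0), 1)
  }
  out
}

#' Select the red, green, and blue bands from a multispectral stack
#'
#' @param ms H x W x B array.
#' @param band_map Named integer vector with entries `red`, `green`, `blue`
#'   giving 1-based band indices.
#' @return H x W x 3 array in R, G, B order.
#' @export
extract_rgb <- function(ms, band_map = c(red = 1L, green = 2L, blue = 3L)) {
  stopifnot(length(dim(ms)) == 3)
  need <- c("red", "green", "blue")
  if (!all(need %in% names(band_map)))
    stop("band_map must name red, green and blue bands")
  idx <- as.integer(band_map[need])
  if (any(idx < 1) || any(idx > dim(ms)[3]))
    stop("band_map references band outside 1..", dim(ms)[3])
  ms[, , idx, drop = FALSE]
}

#' Define a tile grid over a raster
#'
#' @param tile_px Tile side in pixels (default 32, the survey's
#'   classification unit).
#' @param stride_px Stride between tile origins; equal to `tile_px` for a
#'   disjoint partition, smaller for overlapping tiles.
#' @param origin Integer `(row0, col0)` 0-based pixel offset of the first
#'   tile.
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(tile_px = 32L, stride_px = tile_px, origin = c(0L, 0L)) {
  stopifnot(tile_px >= 1, stride_px >= 1, stride_px <= tile_px,
            length(origin) == 2, all(origin >= 0))
  structure(list(tile_px = as.integer(tile_px),
                 stride_px = as.integer(stride_px),
                 origin = as.integer(origin)),
            class = "tile_grid")
}

# Number of tile rows/cols for an extent of n pixels under a grid.
grid_count <- function(n, origin, tile_px, stride_px) {
  avail <- n - origin - tile_px
  if (avail < 0) 0L else as.integer(floor(avail / stride_px) + 1L)
}

#' Split a scene into fixed-size tiles
#'
#' Tiles are enumerated row-major from the grid origin; trailing partial
#' strips that cannot hold a full tile are dropped, so every emitted tile is
#' exactly `tile_px` square. With `stride_px == tile_px` the tiles partition
#' the covered region disjointly.
#'
#' @param scene A `whale_scene`, or a bare H x W x C array.
#' @param grid A [tile_grid()].
#' @return List of `tile` objects, each with `pixels`, `grid_pos`
#'   (0-based `c(row, col)`), `parent_scene_id`, and `gsd_m`.
#' @export
tile_scene <- function(scene, grid = tile_grid()) {
  stopifnot(inherits(grid, "tile_grid"))
  if (inherits(scene, "whale_scene")) {
    px <- scene$pixels; sid <- scene$scene_id; gsd <- scene$gsd_m
  } else {
    px <- scene; sid <- "raster"; gsd <- NA_real_
  }
  d <- dim(px)
  tp <- grid$tile_px; st <- grid$stride_px
  nr <- grid_count(d[1], grid$origin[1], tp, st)
  nc <- grid_count(d[2], grid$origin[2], tp, st)
  if (nr < 1 || nc < 1)
    stop("scene (", d[1], " x ", d[2], ") smaller than one ", tp, "-px tile")
  tiles <- vector("list", nr * nc)
  i <- 0L
  for (r in seq_len(nr) - 1L) {
    r0 <- grid$origin[1] + r * st
    for (cc in seq_len(nc) - 1L) {
      c0 <- grid$origin[2] + cc * st
      i <- i + 1L
      tiles[[i]] <- structure(list(
        pixels = px[(r0 + 1):(r0 + tp), (c0 + 1):(c0 + tp), , drop = FALSE],
        grid_pos = c(row = r, col = cc),
        parent_scene_id = sid, gsd_m = gsd
      ), class = "tile")
    }
  }
  attr(tiles, "grid") <- grid
  attr(tiles, "n_rows") <- nr
  attr(tiles, "n_cols") <- nc
  tiles
}

#' Ground footprint of a square tile
#'
#' @param tile_px Tile side in pixels.
#' @param gsd_m Ground-sample distance in metres per pixel.
#' @return Tile area in square metres, `(tile_px * gsd_m)^2`. A 32-px tile
#'   at 0.31 m/px covers 98.4 m^2.
#' @export
tile_area_m2 <- function(tile_px, gsd_m) {
  stopifnot(tile_px >= 1, gsd_m > 0)
  (tile_px * gsd_m)^2
}

#' Enlarge a tile to a network input size
#'
#' Interpolated enlargement of a tile (32 -> 224 px for standard
#' classification backbones). Shrinking is refused.
#'
#' @param tile A `tile` object or bare array.
#' @param out_px Output side in pixels, `>=` the tile's.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return Tile (or array) at `out_px` square; values stay in the input
#'   range. `out_px` equal to the current size is the identity.
#' @export
upscale_tile <- function(tile, out_px, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  px <- if (inherits(tile, "tile")) tile$pixels else tile
  d <- dim(px)
  if (d[1] != d[2]) stop("tile must be square")
  if (out_px < d[1])
    stop("out_px (", out_px, ") smaller than tile (", d[1],
         "); shrinking is not an enlargement")
  out <- if (out_px == d[1]) px else resize_raster(px, out_px, out_px, method)
  if (inherits(tile, "tile")) { tile$pixels <- out; tile } else out
}
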