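#' Parameters for a synthetic ocean scene
#'
#' Describes one seeded ocean scene: raster geometry, ground-sample distance
#' (GSD), sea state, and the whale targets to embed. Scenes emulate the two
#' imagery sources of a whale survey: fine-GSD aerial frames (~2 cm/px) and
#' satellite panchromatic-resolution frames (~31 cm/px).
#'
#' @param width_px,height_px Scene dimensions in pixels (both >= 32).
#' @param gsd_m Ground-sample distance in metres per pixel (> 0).
#' @param sea_state Ordinal 0--5: 0 is flat calm, 5 heavy whitecaps.
#'   Whitecap speckle density grows with sea state; above Beaufort-4
#'   conditions visual whale detection degrades, and the generator mimics
#'   that regime at levels 4--5.
#' @param n_whales Number of distinct individuals to place (>= 0).
#' @param whale_length_m Length-sampling interval `c(min, max)` in metres.
#'   Default 7--9 m ("minke-like"); satellite test scenes typically use
#'   12--16 m ("right/humpback-like"). These are generator knobs, not
#'   biological claims.
#' @param n_duplicate_frames Frames per individual (>= 1). Aerial surveys
#'   image the same whale several times from successive camera frames; each
#'   duplicate is rendered at a jittered pose and position but shares its
#'   `individual_id`.
#' @param distractors Character subset of `c("boat", "detritus")`: bright
#'   non-whale objects rendered without instance records.
#' @param contrast Mean whale-vs-water intensity offset (whales darker);
#'   default 0.15 with per-pixel jitter. Lower values make harder scenes.
#' @param n_ms_bands If > 0, also emit a coarse multispectral stack
#'   (`n_ms_bands` bands at 4x coarser grid) plus a fine panchromatic band,
#'   mirroring the 124 cm multispectral / 31 cm panchromatic pairing of a
#'   very high-resolution satellite sensor. Requires dimensions divisible
#'   by 4.
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   scenes.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(width_px, height_px, gsd_m,
                         sea_state = 0L,
                         n_whales = 0L,
                         whale_length_m = c(7, 9),
                         n_duplicate_frames = 1L,
                         distractors = character(),
                         contrast = 0.15,
                         n_ms_bands = 0L,
                         seed = 1L) {
  stopifnot(is.numeric(width_px), is.numeric(height_px))
  if (width_px < 32 || height_px < 32)
    stop("scene dimensions must be at least 32 px in each direction")
  if (!is.numeric(gsd_m) || length(gsd_m) != 1 || gsd_m <= 0)
    stop("gsd_m must be a single positive number (metres per pixel)")
  if (!sea_state %in% 0:5)
    stop("sea_state must be an integer in 0..5")
  if (n_whales < 0) stop("n_whales must be >= 0")
  if (length(whale_length_m) != 2 || any(whale_length_m <= 0) ||
      whale_length_m[1] > whale_length_m[2])
    stop("whale_length_m must be a positive ordered interval c(min, max)")
  if (n_duplicate_frames < 1) stop("n_duplicate_frames must be >= 1")
  bad <- setdiff(distractors, c("boat", "detritus"))
  if (length(bad)) stop("unknown distractors: ", paste(bad, collapse = ", "))
  if (n_ms_bands > 0 && (width_px %% 4 != 0 || height_px %% 4 != 0))
    stop("multispectral scenes need dimensions divisible by 4")
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    gsd_m = gsd_m, sea_state = as.integer(sea_state),
    n_whales = as.integer(n_whales), whale_length_m = as.numeric(whale_length_m),
    n_duplicate_frames = as.integer(n_duplicate_frames),
    distractors = distractors, contrast = contrast,
    n_ms_bands = as.integer(n_ms_bands), seed = as.integer(seed)
  ), class = "scene_params")
}

# Run expr with a private RNG stream so scene generation never perturbs the
# caller's random state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Low-frequency noise field: coarse iid grid upsampled bilinearly to (h, w).
smooth_noise <- function(h, w, cell = 16) {
  ch <- max(2L, ceiling(h / cell) + 1L)
  cw <- max(2L, ceiling(w / cell) + 1L)
  g <- matrix(stats::rnorm(ch * cw), ch, cw)
  resize_raster(g, h, w, method = "bilinear")
}

# Elliptical whale silhouette with a perpendicular fluke lobe at the tail.
# Body spans [-0.38, +0.50] L along the major axis, fluke [-0.50, -0.38] L,
# so the total major-axis extent is exactly the drawn length. Returns a
# soft coverage raster in [0, 1]; the binary mask is coverage >= 0.5.
# Closed-form area of the drawn shape (two disjoint ellipses):
#   pi * (0.44 * 0.10 + 0.06 * 0.16) * L^2  =  0.16839 L^2  (pixels of L px)
whale_coverage <- function(h, w, cy, cx, length_px, pose_deg) {
  th <- pose_deg * pi / 180
  co <- cos(th); si <- sin(th)
  L <- length_px
  # rotated local coordinates (u along major axis, v across)
  x <- matrix(rep(seq_len(w), each = h), h, w) - cx
  y <- matrix(rep(seq_len(h), times = w), h, w) - cy
  u <- x * co + y * si
  v <- -x * si + y * co
  soft <- function(e, bpx) pmin(pmax((1 - sqrt(e)) * bpx + 0.5, 0), 1)
  # body ellipse: centre +0.06 L, semi-axes 0.44 L x 0.10 L
  eb <- ((u - 0.06 * L) / (0.44 * L))^2 + (v / (0.10 * L))^2
  # fluke: centre -0.44 L, semi-axes 0.06 L (along) x 0.16 L (across)
  ef <- ((u + 0.44 * L) / (0.06 * L))^2 + (v / (0.16 * L))^2
  pmax(soft(eb, 0.10 * L), soft(ef, 0.06 * L))
}

whale_shape_area_px2 <- function(length_px) {
  pi * (0.44 * 0.10 + 0.06 * 0.16) * length_px^2
}

#' Generate a seeded synthetic ocean scene
#'
#' Renders a reflectance-like `[0, 1]` RGB raster of open water with optional
#' whale targets, duplicate frames, distractor objects, and (optionally) a
#' paired coarse multispectral stack + fine panchromatic band. The water
#' texture combines a low-frequency swell field, directional wave streaks,
#' fine pixel noise, and Bernoulli whitecap speckle whose rate grows with
#' `sea_state`. Whales are rendered darker than the local water surface by
#' `params$contrast` (with per-pixel jitter) and carry per-instance binary
#' masks.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `whale_scene`: a list with elements `pixels`
#'   (H x W x 3 array in `[0, 1]`), `gsd_m`, `whales` (list of
#'   `whale_instance`, each with `instance_id`, `individual_id`, `mask`,
#'   `length_m`, `pose_deg`), `ms`/`pan` (when configured), `scene_id`, and
#'   `params`.
#' @examples
#' sc <- generate_scene(scene_params(64, 64, gsd_m = 0.31, sea_state = 1,
#'                                   n_whales = 1, whale_length_m = c(12, 14),
#'                                   seed = 3))
#' range(sc$pixels)
#' sum(sc$whales[[1]]$mask)
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$height_px; w <- params$width_px
  max_len_px <- params$whale_length_m[2] / params$gsd_m
  if (params$n_whales > 0 && max_len_px >= min(h, w))
    stop("whale longer than scene extent: max length ",
         params$whale_length_m[2], " m is ", round(max_len_px),
         " px at gsd ", params$gsd_m, " m/px")
  with_seed(params$seed, {
    ss <- params$sea_state
    # swell and streak structure has physical scale (metres), so aerial
    # scenes down-sampled to satellite GSD match native satellite texture
    swell_cell_px <- max(2, 6 / params$gsd_m)    # ~6 m swell patches
    base <- 0.45 +
      (0.015 + 0.012 * ss) * smooth_noise(h, w, cell = swell_cell_px) +
      0.01 * matrix(stats::rnorm(h * w), h, w)
    # directional wave streaks, wavelength ~2.5-5.5 m
    if (ss > 0) {
      th <- stats::runif(1, 0, pi)
      lam <- stats::runif(1, 2.5, 5.5) / params$gsd_m
      ph <- stats::runif(1, 0, 2 * pi)
      gx <- matrix(rep(seq_len(w), each = h), h, w)
      gy <- matrix(rep(seq_len(h), times = w), h, w)
      base <- base + (0.004 + 0.01 * ss) *
        sin(2 * pi * (gx * cos(th) + gy * sin(th)) / lam + ph)
    }
    base <- pmin(0.85, pmax(0.05, base))
    # whitecap speckle: rate strictly increasing in sea state
    if (ss > 0) {
      p_cap <- 0.0035 * ss
      caps <- stats::runif(h * w) < p_cap
      base[caps] <- stats::runif(sum(caps), 0.92, 1)
    }

    whales <- list()
    cover_all <- matrix(0, h, w)
    inst <- 0L
    if (params$n_whales > 0) {
      margin <- max_len_px / 2 + 2
      for (ind in seq_len(params$n_whales) - 1L) {
        len_m <- stats::runif(1, params$whale_length_m[1], params$whale_length_m[2])
        for (fr in seq_len(params$n_duplicate_frames)) {
          len_px <- len_m / params$gsd_m
          pose <- stats::runif(1, 0, 360)
          cy <- stats::runif(1, margin, h - margin)
          cx <- stats::runif(1, margin, w - margin)
          cov <- whale_coverage(h, w, cy, cx, len_px, pose)
          whales[[length(whales) + 1L]] <- structure(list(
            instance_id = inst, individual_id = ind,
            mask = cov >= 0.5, length_m = len_m, pose_deg = pose %% 360
          ), class = "whale_instance")
          cover_all <- pmax(cover_all, cov)
          inst <- inst + 1L
        }
      }
    }

    # distractors: bright elongated objects with no instance record
    if ("boat" %in% params$distractors) {
      blen <- stats::runif(1, 10, 20) / params$gsd_m
      blen <- min(blen, min(h, w) / 2)
      bcov <- whale_coverage(h, w,
                             stats::runif(1, blen, h - blen),
                             stats::runif(1, blen, w - blen),
                             blen, stats::runif(1, 0, 360))
      base[bcov >= 0.5] <- stats::runif(sum(bcov >= 0.5), 0.9, 1)
    }
    if ("detritus" %in% params$distractors) {
      n_d <- 8L
      dy <- sample.int(h, n_d); dx <- sample.int(w, n_d)
      base[cbind(dy, dx)] <- stats::runif(n_d, 0.75, 0.9)
    }

    # composite whales (darker than local water, jittered)
    whale_tone <- base - params$contrast +
      0.02 * matrix(stats::rnorm(h * w), h, w)
    gray <- base * (1 - cover_all) + whale_tone * cover_all
    gray <- pmin(pmax(gray, 0), 1)

    # slight per-channel tint around the grayscale field
    tint <- c(0.97, 1.00, 1.03)
    px <- array(0, c(h, w, 3))
    for (b in 1:3) px[, , b] <- pmin(pmax(gray * tint[b], 0), 1)

    ms <- NULL; pan <- NULL
    if (params$n_ms_bands > 0) {
      B <- params$n_ms_bands
      bt <- seq(0.9, 1.1, length.out = B)
      fine <- array(0, c(h, w, B))
      for (b in seq_len(B)) fine[, , b] <- pmin(pmax(gray * bt[b], 0), 1)
      pan <- apply(fine, c(1, 2), mean)
      ms <- array(0, c(h / 4, w / 4, B))
      for (b in seq_len(B)) ms[, , b] <- area_downsample(fine[, , b], h / 4, w / 4)
    }

    structure(list(
      pixels = px, gsd_m = params$gsd_m, whales = whales,
      ms = ms, pan = pan,
      scene_id = sprintf("scene_%08x", params$seed %% .Machine$integer.max),
      params = params
    ), class = "whale_scene")
  })
}

#' @export
print.whale_scene <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<whale_scene %s: %d x %d px @ %.3g m/px, %d whale instance(s), sea state %d>\n",
              x$scene_id, d[1], d[2], x$gsd_m, length(x$whales),
              x$params$sea_state))
  invisible(x)
}

#' Generate paired aerial and satellite scene collections
#'
#' Emulates the two-branch survey design: a fine-GSD aerial collection used
#' for training (after down-sampling to satellite GSD) and a coarse-GSD
#' satellite collection used for testing. Scene seeds are derived
#' deterministically from each parameter set's base seed, so identical
#' inputs give bit-identical collections.
#'
#' @param aerial A [scene_params()] for the aerial branch; its `gsd_m` must
#'   be strictly finer (smaller) than the satellite branch's.
#' @param satellite A [scene_params()] for the satellite branch.
#' @param n_aerial,n_satellite Number of scenes per branch.
#' @return A list with elements `aerial` and `satellite`, each a list of
#'   `whale_scene` objects.
#' @export
generate_paired_survey <- function(aerial, satellite,
                                   n_aerial = 1L, n_satellite = 1L) {
  stopifnot(inherits(aerial, "scene_params"), inherits(satellite, "scene_params"))
  if (aerial$gsd_m >= satellite$gsd_m)
    stop("aerial GSD (", aerial$gsd_m, ") must be finer than satellite GSD (",
         satellite$gsd_m, ")")
  gen <- function(base, n) {
    lapply(seq_len(n), function(i) {
      p <- base
      p$seed <- as.integer((base$seed + 7919L * i) %% .Machine$integer.max)
      generate_scene(p)
    })
  }
  list(aerial = gen(aerial, n_aerial), satellite = gen(satellite, n_satellite))
}

#' Whitecap pixel fraction of a scene
#'
#' Fraction of pixels brighter than `threshold` (default 0.9) in the first
#' channel; the summary statistic used to check that surface roughness grows
#' with sea state.
#' @param scene A `whale_scene`.
#' @param threshold Intensity above which a pixel counts as whitecap.
#' @export
whitecap_fraction <- function(scene, threshold = 0.9) {
  mean(scene$pixels[, , 1] > threshold)
}
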