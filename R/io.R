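# Plain-text/raster interchange: scenes as 8-bit PNG with a JSON sidecar
# carrying the ground-sample distance and generator parameters, instance
# masks as single-channel label PNGs (0 = water, k = instance k), and CSV
# manifests.

#' Write a scene to disk
#'
#' Writes `<name>.png` (8-bit RGB), `<name>_mask.png` (single-channel label
#' raster, instance k stored as intensity k/255), and `<name>.json`
#' (GSD, seed, generator parameters, instance metadata).
#'
#' @param scene A `whale_scene`.
#' @param dir Output directory (created if needed).
#' @param name Basename; defaults to the scene id.
#' @return Invisibly, the sidecar path.
#' @export
write_scene <- function(scene, dir, name = scene$scene_id) {
  stopifnot(inherits(scene, "whale_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(scene$pixels, file.path(dir, paste0(name, ".png")))
  h <- dim(scene$pixels)[1]; w <- dim(scene$pixels)[2]
  lab <- matrix(0, h, w)
  for (wi in scene$whales)
    lab[(wi$mask + 0) >= 0.5] <- (wi$instance_id + 1) / 255
  png::writePNG(lab, file.path(dir, paste0(name, "_mask.png")))
  meta <- list(
    scene_id = name, gsd_m = scene$gsd_m,
    seed = scene$params$seed,
    params = unclass(scene$params),
    instances = lapply(scene$whales, function(wi)
      list(instance_id = wi$instance_id, individual_id = wi$individual_id,
           length_m = wi$length_m, pose_deg = wi$pose_deg))
  )
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir Directory holding the PNG/JSON triplet.
#' @param name Scene basename.
#' @return A `whale_scene` (pixels quantized to 8 bits; masks binary).
#' @export
read_scene <- function(dir, name) {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  px <- png::readPNG(file.path(dir, paste0(name, ".png")))
  lab <- png::readPNG(file.path(dir, paste0(name, "_mask.png")))
  whales <- list()
  if (length(meta$instances)) {
    inst <- meta$instances
    for (i in seq_len(nrow(inst))) {
      k <- inst$instance_id[i] + 1
      whales[[i]] <- structure(list(
        instance_id = inst$instance_id[i],
        individual_id = inst$individual_id[i],
        mask = abs(lab * 255 - k) < 0.5,
        length_m = inst$length_m[i], pose_deg = inst$pose_deg[i]
      ), class = "whale_instance")
    }
  }
  p <- meta$params
  params <- scene_params(p$width_px, p$height_px, p$gsd_m, p$sea_state,
                         p$n_whales, unlist(p$whale_length_m),
                         p$n_duplicate_frames, unlist(p$distractors),
                         p$contrast, p$n_ms_bands, p$seed)
  structure(list(pixels = px, gsd_m = meta$gsd_m, whales = whales,
                 ms = NULL, pan = NULL, scene_id = meta$scene_id,
                 params = params),
            class = "whale_scene")
}

#' Write a scene collection manifest
#'
#' One row per instance (plus one row for instance-free scenes), listing
#' scene id, GSD, sea state, and instance metadata.
#'
#' @param scenes List of `whale_scene`.
#' @param path CSV path.
#' @return Invisibly, the manifest data frame.
#' @export
write_scene_manifest <- function(scenes, path) {
  rows <- lapply(scenes, function(sc) {
    if (!length(sc$whales))
      return(data.frame(scene_id = sc$scene_id, gsd_m = sc$gsd_m,
                        sea_state = sc$params$sea_state,
                        instance_id = NA_integer_, individual_id = NA_integer_,
                        length_m = NA_real_, pose_deg = NA_real_))
    do.call(rbind, lapply(sc$whales, function(wi)
      data.frame(scene_id = sc$scene_id, gsd_m = sc$gsd_m,
                 sea_state = sc$params$sea_state,
                 instance_id = wi$instance_id,
                 individual_id = wi$individual_id,
                 length_m = wi$length_m, pose_deg = wi$pose_deg)))
  })
  man <- do.call(rbind, rows)
  utils::write.csv(man, path, row.names = FALSE)
  invisible(man)
}

#' Export tiles as PNG files with a manifest
#'
#' Tiles are written as `{scene}_{row}_{col}.png`; the manifest CSV lists
#' `scene_id, row, col, label, whale_fraction, retained, path`.
#'
#' @param dataset A `tile_dataset` with pixel data.
#' @param dir Output directory.
#' @return Invisibly, the manifest data frame.
#' @export
write_tiles <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tile_dataset"), !is.null(dataset$tiles))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- dataset$manifest
  paths <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    fn <- sprintf("%s_%d_%d.png", m$scene_id[i], m$row[i], m$col[i])
    png::writePNG(dataset$tiles[[i]]$pixels, file.path(dir, fn))
    paths[i] <- fn
  }
  man <- cbind(m, path = paths)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
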