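# End-to-end experiment recipes: synthetic survey -> prepare -> train ->
# evaluate -> report, plus the k-fold and learning-rate-sweep recipes and
# the triage step that ranks satellite tiles for expert review.

#' Experiment configuration
#'
#' A single serializable object from which a whole run is reproducible:
#' scene parameters for both survey branches, tiling grid, retention
#' threshold, training configuration, baseline configurations, and the
#' master seed.
#'
#' @param aerial,satellite [scene_params()] for the two branches; the
#'   aerial GSD must be finer than the satellite GSD.
#' @param n_aerial_whale,n_aerial_water Number of aerial scenes with and
#'   without whales.
#' @param n_satellite_whale,n_satellite_water Satellite scene counts.
#' @param grid A [tile_grid()].
#' @param retention_threshold Minimum whale fraction for a whale tile.
#' @param train A [train_config()].
#' @param baselines List of [baseline_config()]s.
#' @param water_test_n Optional cap on satellite water test tiles
#'   (uniform subsample; NULL keeps all).
#' @param seed Master seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(aerial, satellite,
                              n_aerial_whale = 20L, n_aerial_water = 10L,
                              n_satellite_whale = 8L, n_satellite_water = 8L,
                              grid = tile_grid(32L),
                              retention_threshold = 0.20,
                              train = train_config(),
                              baselines = list(baseline_config("ridge"),
                                               baseline_config("c_svc")),
                              water_test_n = NULL,
                              seed = 1L) {
  stopifnot(inherits(aerial, "scene_params"), inherits(satellite, "scene_params"),
            inherits(grid, "tile_grid"), inherits(train, "train_config"))
  if (aerial$gsd_m >= satellite$gsd_m)
    stop("aerial GSD (", aerial$gsd_m,
         ") must be finer than satellite GSD (", satellite$gsd_m, ")")
  structure(list(aerial = aerial, satellite = satellite,
                 n_aerial_whale = as.integer(n_aerial_whale),
                 n_aerial_water = as.integer(n_aerial_water),
                 n_satellite_whale = as.integer(n_satellite_whale),
                 n_satellite_water = as.integer(n_satellite_water),
                 grid = grid, retention_threshold = retention_threshold,
                 train = train, baselines = baselines,
                 water_test_n = water_test_n, seed = as.integer(seed)),
            class = "experiment_config")
}

#' The shipped quickstart configuration
#'
#' A desk-scale configuration: the compact backbone, easy sea conditions,
#' and scene counts sized so the whole recipe runs on one CPU in minutes.
#' Aerial scenes are generated at 7.75 cm GSD (4x finer than the satellite
#' branch's 31 cm) and down-sampled for training; satellite test scenes
#' carry larger whales, mirroring the train-on-small / test-on-large design
#' of a real survey.
#'
#' @param seed Master seed.
#' @param sea_state Sea state for both branches (default 1).
#' @param contrast Whale/water contrast margin (default 0.15).
#' @return An [experiment_config()].
#' @export
quickstart_config <- function(seed = 1L, sea_state = 1L, contrast = 0.15) {
  aerial <- scene_params(288, 288, gsd_m = 0.0775, sea_state = sea_state,
                         n_whales = 1, whale_length_m = c(7, 9),
                         n_duplicate_frames = 2, contrast = contrast,
                         seed = seed)
  satellite <- scene_params(96, 96, gsd_m = 0.31, sea_state = sea_state,
                            n_whales = 1, whale_length_m = c(12, 16),
                            contrast = contrast, seed = seed + 1000L)
  experiment_config(
    aerial, satellite,
    n_aerial_whale = 24L, n_aerial_water = 12L,
    n_satellite_whale = 10L, n_satellite_water = 10L,
    train = train_config("smallnet", learning_rate = 0.02, momentum = 0.9,
                         step_size_epochs = 7L, decay_factor = 0.1,
                         batch_size = 16L, n_epochs = 12L,
                         sampler = "weighted", input_px = 32L, seed = seed),
    seed = seed
  )
}

# Generate one survey branch: scenes with whales plus water-only scenes,
# each scene seeded deterministically from the branch parameters.
branch_scenes <- function(params, n_whale_scenes, n_water_scenes, seed_shift) {
  gen <- function(p, n, shift) {
    lapply(seq_len(n), function(i) {
      q <- p
      q$seed <- as.integer((p$seed + shift + 7919L * i) %% .Machine$integer.max)
      generate_scene(q)
    })
  }
  water_params <- params
  water_params$n_whales <- 0L
  c(gen(params, n_whale_scenes, seed_shift),
    gen(water_params, n_water_scenes, seed_shift + 104729L))
}

# Tile + label a list of scenes into one dataset. Satellite scenes with a
# multispectral stack are pansharpened and reduced to RGB first; aerial
# scenes are down-sampled to the target GSD.
prepare_branch <- function(scenes, grid, threshold, target_gsd = NULL) {
  all_tiles <- list()
  manifests <- list()
  for (sc in scenes) {
    if (!is.null(target_gsd)) sc <- bilinear_downsample(sc, target_gsd)
    if (!is.null(sc$ms)) {
      ps <- gram_schmidt_pansharpen(sc$ms, sc$pan)
      sc$pixels <- extract_rgb(ps)
    }
    tiles <- tile_scene(sc, grid)
    man <- assign_labels(tiles, sc$whales, threshold)
    all_tiles <- c(all_tiles, tiles)
    manifests[[length(manifests) + 1L]] <- man
  }
  tile_dataset(all_tiles, do.call(rbind, manifests))
}

#' Run the full experiment recipe
#'
#' Executes the whole pipeline: generate both survey branches, down-sample
#' the aerial branch to satellite GSD, (pansharpen the satellite branch
#' when multispectral), tile, label under the retention rule, subsample the
#' water test pool, train with per-epoch evaluation on the satellite test
#' set, select the best epoch, fit and evaluate the classical baselines on
#' the balanced subset, and write reports.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory for manifests and report CSVs; NULL
#'   (default) skips writing.
#' @return List with `train_set`, `test_set`, `model` (best-epoch weights),
#'   `metrics` (per-epoch), `best_epoch`, `cnn` (metric report row),
#'   `baselines` (table), `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  aerial_scenes <- branch_scenes(config$aerial, config$n_aerial_whale,
                                 config$n_aerial_water, 0L)
  sat_scenes <- branch_scenes(config$satellite, config$n_satellite_whale,
                              config$n_satellite_water, 500000L)
  train_set <- prepare_branch(aerial_scenes, config$grid,
                              config$retention_threshold,
                              target_gsd = config$satellite$gsd_m)
  test_set <- prepare_branch(sat_scenes, config$grid,
                             config$retention_threshold)
  if (!is.null(config$water_test_n) &&
      config$water_test_n < test_set$counts[["water"]])
    test_set <- subsample_class(test_set, "water", config$water_test_n,
                                seed = config$seed)
  if (min(train_set$counts) == 0)
    stop("aerial training set is missing a class; enlarge the scene set")

  model <- build_model(config$train)
  model <- train(model, train_set, test_set, config$train)
  model <- restore_best_epoch(model)
  best <- model$best_epoch
  cnn_cm <- eval_metrics(model$layers,
                         dataset_tensor(test_set, config$train$input_px,
                                        norm = model$norm))$cm
  cnn_row <- cbind(data.frame(model = config$train$architecture,
                              epoch = best, stringsAsFactors = FALSE),
                   metric_report(cnn_cm))

  bal <- balanced_subset(train_set, seed = config$seed)
  hp <- hog_params()
  tr_hog <- hog_dataset(bal, hp)
  te_hog <- hog_dataset(test_set, hp)
  base_rows <- lapply(config$baselines, function(bc) {
    fit <- fit_baseline(tr_hog$features, tr_hog$labels, bc)
    cm <- evaluate_baseline(fit, te_hog$features, te_hog$labels)
    cbind(data.frame(model = bc$model, epoch = NA_integer_,
                     stringsAsFactors = FALSE), metric_report(cm))
  })
  comparison <- rbind(cnn_row, do.call(rbind, base_rows))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(model$metrics,
                     file.path(out_dir, "epoch_metrics.csv"), row.names = FALSE)
    utils::write.csv(comparison,
                     file.path(out_dir, "model_comparison.csv"), row.names = FALSE)
    utils::write.csv(train_set$manifest,
                     file.path(out_dir, "train_manifest.csv"), row.names = FALSE)
    utils::write.csv(test_set$manifest,
                     file.path(out_dir, "test_manifest.csv"), row.names = FALSE)
    jsonlite::write_json(config_to_list(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(train_set = train_set, test_set = test_set, model = model,
       metrics = model$metrics, best_epoch = best,
       cnn = cnn_row, baselines = do.call(rbind, base_rows),
       comparison = comparison, confusion = cnn_cm, config = config)
}

#' Rotate-the-fold validation recipe
#'
#' Builds the aerial dataset once, splits it into stratified folds, and
#' trains/evaluates one model per fold (testing on the held-out fold).
#'
#' @param config An [experiment_config()].
#' @param n_folds Number of folds (default 10; desk-scale runs use fewer).
#' @param unit `"frame"` or `"individual"` (see [make_folds()]).
#' @return List with `report` ([fold_report()] table) and `cms`.
#' @export
run_kfold <- function(config, n_folds = 10L, unit = "frame") {
  stopifnot(inherits(config, "experiment_config"))
  aerial_scenes <- branch_scenes(config$aerial, config$n_aerial_whale,
                                 config$n_aerial_water, 0L)
  ds <- prepare_branch(aerial_scenes, config$grid,
                       config$retention_threshold,
                       target_gsd = config$satellite$gsd_m)
  folds <- make_folds(ds, n_folds = n_folds, unit = unit, seed = config$seed)
  cms <- lapply(seq_len(n_folds), function(k) {
    sp <- fold_split(ds, folds, k)
    m <- build_model(config$train)
    m <- train(m, sp$train, sp$test, config$train)
    m <- restore_best_epoch(m)
    eval_metrics(m$layers, dataset_tensor(sp$test, config$train$input_px,
                                          norm = m$norm))$cm
  })
  list(report = fold_report(cms), cms = cms, folds = folds)
}

#' Learning-rate sweep recipe
#'
#' Trains one model per learning rate on a fixed train/test split and
#' tabulates best-epoch water-positive metrics.
#'
#' @param config An [experiment_config()].
#' @param learning_rates Numeric vector of rates to sweep.
#' @return An [lr_sweep_report()] table.
#' @export
run_lr_sweep <- function(config, learning_rates) {
  stopifnot(inherits(config, "experiment_config"), length(learning_rates) >= 1)
  rows <- lapply(learning_rates, function(lr) {
    cf <- config
    cf$train$learning_rate <- lr
    res <- run_experiment(cf)
    data.frame(learning_rate = lr,
               precision = res$cnn$precision, recall = res$cnn$recall)
  })
  lr_sweep_report(do.call(rbind, rows))
}

#' Triage satellite scenes for expert review
#'
#' Tiles each scene, scores every tile with the trained model, and returns
#' the tiles with `p_whale` above the threshold, ranked most-suspicious
#' first, with scene coordinates so an analyst can jump straight to them.
#' The intent is semi-automated survey: the model eliminates the empty
#' ocean, the expert confirms the rest.
#'
#' @param model A trained `whale_model`.
#' @param scenes List of `whale_scene` (at the model's working GSD).
#' @param grid A [tile_grid()].
#' @param threshold Minimum `p_whale` to report (1.0 reports nothing, 0.0
#'   everything).
#' @return Data frame `scene_id, row, col, p_whale`, sorted by descending
#'   `p_whale`.
#' @export
triage <- function(model, scenes, grid = tile_grid(32L), threshold = 0.5) {
  stopifnot(inherits(model, "whale_model"))
  if (!isTRUE(model$trained)) stop("model has not been trained")
  rows <- lapply(scenes, function(sc) {
    tiles <- tile_scene(sc, grid)
    pred <- predict_tiles(model, tiles)
    data.frame(scene_id = sc$scene_id,
               row = vapply(tiles, function(t) t$grid_pos[["row"]], 0L),
               col = vapply(tiles, function(t) t$grid_pos[["col"]], 0L),
               p_whale = pred$p_whale, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- if (threshold <= 0) rep(TRUE, nrow(out)) else out$p_whale > threshold
  out <- out[keep, , drop = FALSE]
  out[order(-out$p_whale), , drop = FALSE]
}

# Serializable view of an experiment config (for the run snapshot).
config_to_list <- function(config) {
  l <- unclass(config)
  l$aerial <- unclass(l$aerial)
  l$satellite <- unclass(l$satellite)
  l$grid <- unclass(l$grid)
  l$train <- unclass(l$train)
  l$baselines <- lapply(l$baselines, unclass)
  l
}

#' Write / read experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `write_config` returns the path invisibly; `read_config` an
#'   [experiment_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  l <- yaml::read_yaml(path)
  sp <- function(p) scene_params(p$width_px, p$height_px, p$gsd_m, p$sea_state,
                                 p$n_whales, unlist(p$whale_length_m),
                                 p$n_duplicate_frames,
                                 unlist(p$distractors) %||% character(),
                                 p$contrast, p$n_ms_bands, p$seed)
  experiment_config(
    aerial = sp(l$aerial), satellite = sp(l$satellite),
    n_aerial_whale = l$n_aerial_whale, n_aerial_water = l$n_aerial_water,
    n_satellite_whale = l$n_satellite_whale,
    n_satellite_water = l$n_satellite_water,
    grid = tile_grid(l$grid$tile_px, l$grid$stride_px, unlist(l$grid$origin)),
    retention_threshold = l$retention_threshold,
    train = do.call(train_config, l$train[setdiff(names(l$train), character())]),
    baselines = lapply(l$baselines, function(b)
      baseline_config(b$model, b$alpha, b$C, b$kernel, b$seed)),
    water_test_n = l$water_test_n, seed = l$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
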