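test_that("every architecture builds a 2-logit head; pretrained errors explicitly", {
  for (arch in c("smallnet", "resnet18", "resnet34", "resnet152", "densenet")) {
    m <- build_model(train_config(arch, seed = 1))
    expect_equal(whaletiles:::nn_head_dim(m$layers), 2L)
  }
  expect_error(build_model(train_config("resnet18", pretrained = TRUE)),
               "pretrained")
  expect_error(train_config("alexnet"))
})

test_that("seeded initialization gives deterministic logits and valid probabilities", {
  set.seed(99)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  m1 <- build_model(train_config("smallnet", input_px = 32, seed = 7))
  m2 <- build_model(train_config("smallnet", input_px = 32, seed = 7))
  l1 <- whaletiles:::nn_forward(m1$layers, x)$out
  expect_identical(l1, whaletiles:::nn_forward(m2$layers, x)$out)
  m3 <- build_model(train_config("smallnet", input_px = 32, seed = 8))
  expect_false(identical(l1, whaletiles:::nn_forward(m3$layers, x)$out))
  # a deeper residual backbone runs forward and softmax probabilities sum to 1
  r <- build_model(train_config("resnet18", input_px = 64, seed = 1))
  xr <- array(runif(64 * 64 * 3), c(64, 64, 3, 2))
  pred <- predict_tiles(r, xr)
  expect_true(all(abs(pred$p_water + pred$p_whale - 1) < 1e-6))
  expect_identical(pred, predict_tiles(r, xr))
})

test_that("inverse-frequency weights balance expected batch composition", {
  w <- sample_weights(c(whale = 690, water = 39726))
  expect_equal(w[["whale"]] / w[["water"]], 39726 / 690)
  expect_equal(sample_weights(c(whale = 50, water = 50))[["whale"]],
               sample_weights(c(whale = 50, water = 50))[["water"]])
  expect_error(sample_weights(c(whale = 0, water = 10)), "positive")
  # Monte-Carlo check of the expectation at survey-scale imbalance
  set.seed(1)
  labs <- rep(c(2L, 1L), c(690, 39726))
  wts <- ifelse(labs == 2L, w[["whale"]], w[["water"]])
  shares <- replicate(1000, mean(sample(labs, 32, replace = TRUE,
                                        prob = wts) == 2L))
  expect_lt(abs(mean(shares) - 0.5), 0.01)
})

test_that("learning-rate schedule equals its closed form", {
  expect_equal(lr_schedule(6e-4, 1:24, 7, 0.1),
               6e-4 * 0.1^floor((1:24 - 1) / 7))
  expect_equal(lr_schedule(6e-4, 7, 7, 0.1), 6e-4)   # decay starts at epoch 8
  expect_equal(lr_schedule(6e-4, 8, 7, 0.1), 6e-5)
  set.seed(2)
  for (i in 1:20) {
    base <- runif(1); st <- sample(1:10, 1); dec <- runif(1)
    e <- sample(1:50, 1)
    expect_equal(lr_schedule(base, e, st, dec),
                 base * dec^((e - 1) %/% st))
  }
})

test_that("zero learning rate freezes the model and its metrics", {
  ds <- make_blob_tileset(10, 20, seed = 4)
  cfg <- train_config("smallnet", learning_rate = 0, n_epochs = 3,
                      sampler = "uniform", input_px = 32, batch_size = 8,
                      seed = 3)
  m0 <- build_model(cfg)
  m <- train(m0, ds, ds, cfg)
  expect_identical(m$layers, m0$layers)
  expect_equal(m$metrics$train_loss, rep(m$metrics$train_loss[1], 3))
  expect_equal(m$metrics$f1, rep(m$metrics$f1[1], 3))
})

test_that("smallnet masters an easy separable tile set within 10 epochs", {
  tr <- make_blob_tileset(60, 140, contrast = 0.3, seed = 11)
  te <- make_blob_tileset(30, 70, contrast = 0.3, seed = 12)
  cfg <- train_config("smallnet", learning_rate = 0.02, n_epochs = 10,
                      batch_size = 16, input_px = 32, seed = 5)
  m <- train(build_model(cfg), tr, te, cfg)
  expect_gte(max(m$metrics$train_accuracy), 0.99)
  m <- restore_best_epoch(m)
  pred <- predict_tiles(m, te)
  acc <- mean(pred$label == whaletiles:::retained_manifest(te)$label)
  expect_gte(acc, 0.95)
  # training is reproducible
  m2 <- train(build_model(cfg), tr, te, cfg)
  expect_equal(m$metrics, m2$metrics, tolerance = 1e-12)
})

test_that("training rejects single-class sets", {
  water_only <- make_blob_tileset(0, 20, seed = 1)
  cfg <- train_config("smallnet", n_epochs = 1, input_px = 32, seed = 1)
  expect_error(train(build_model(cfg), water_only, water_only, cfg),
               "both classes")
})

test_that("weighted sampling balances realized batch composition", {
  ds <- make_blob_tileset(8, 120, seed = 6)
  cfg <- train_config("smallnet", learning_rate = 0, n_epochs = 1,
                      sampler = "weighted", input_px = 32, batch_size = 16,
                      seed = 9)
  # measure realized whale share of the sampled stream directly
  tr <- whaletiles:::dataset_tensor(ds, 32)
  w <- sample_weights(c(whale = 8, water = 120))
  wts <- ifelse(tr$y == 2L, w[["whale"]], w[["water"]])
  set.seed(9)
  share <- mean(sample.int(128, 128 * 50, replace = TRUE, prob = wts) <= 8)
  se <- sqrt(0.25 / (128 * 50))
  expect_lt(abs(share - 0.5), 3 * se)
})

test_that("best-epoch selection is an argmax with earliest-tie rule", {
  tr <- data.frame(epoch = 1:3, f1 = c(0.2, 0.9, 0.8))
  expect_equal(select_best_epoch(tr), 2L)
  expect_equal(select_best_epoch(data.frame(epoch = 1:3, f1 = rep(0.5, 3))), 1L)
  expect_equal(select_best_epoch(data.frame(epoch = 1:2, f1 = c(NA, 0.3))), 2L)
  set.seed(3)
  v <- runif(24)
  expect_equal(select_best_epoch(data.frame(epoch = 1:24, f1 = v)),
               which(v == max(v))[1])
})

test_that("prediction vectors are normalized and pure", {
  m <- build_model(train_config("smallnet", input_px = 32, seed = 2))
  x1 <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  x <- array(0, c(32, 32, 3, 3))
  x[, , , 1] <- x1; x[, , , 2] <- x1  # duplicate tile in the batch
  x[, , , 3] <- runif(32 * 32 * 3)
  p <- predict_tiles(m, x)
  expect_true(all(abs(p$p_water + p$p_whale - 1) < 1e-6))
  expect_equal(p[1, ], p[2, ], ignore_attr = TRUE)
  expect_true(all(p$label %in% c("water", "whale")))
})

test_that("performance degrades monotonically as contrast falls to zero", {
  f1s <- vapply(c(0.3, 0.1, 0), function(ct) {
    tr <- make_blob_tileset(40, 80, contrast = ct, noise = 0.05, seed = 21)
    te <- make_blob_tileset(20, 40, contrast = ct, noise = 0.05, seed = 22)
    cfg <- train_config("smallnet", learning_rate = 0.02, n_epochs = 6,
                        batch_size = 16, input_px = 32, seed = 7)
    m <- train(build_model(cfg), tr, te, cfg)
    max(m$metrics$f1, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(f1s) <= 1e-8))
  expect_lt(f1s[3], f1s[1])
})
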