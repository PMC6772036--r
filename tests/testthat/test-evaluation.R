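test_that("confusion counts are exact and conserve the evaluated set", {
  labs <- rep(c("water", "whale"), c(1390, 32))
  # everything correct
  cm <- confusion(labs, labs)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(1390, 0, 0, 32))
  # 87 of 1390 water flagged whale, every whale found
  preds <- c(rep("water", 1303), rep("whale", 87), rep("whale", 32))
  cm2 <- confusion(labs, preds, positive_class = "water")
  expect_equal(c(cm2$tp, cm2$fp, cm2$fn, cm2$tn), c(1303, 0, 87, 32))
  pr <- precision_recall(cm2)
  expect_equal(round(pr[["precision"]], 3), 1.000)
  expect_equal(round(pr[["recall"]], 3), 0.937)
  # water-correct percentage as headline
  expect_equal(round(100 * pr[["recall"]]), 94)
  expect_error(confusion(labs, preds[-1]), "length")
  expect_error(confusion(c("water", "ice"), c("water", "water")), "water")
})

test_that("positive-class swap transposes counts and is an involution", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    labs <- sample(c("water", "whale"), n, replace = TRUE, prob = c(0.8, 0.2))
    preds <- sample(c("water", "whale"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    cm <- confusion(labs, preds, "water")
    sw <- swap_positive(cm)
    expect_equal(c(sw$tp, sw$fp, sw$fn, sw$tn), c(cm$tn, cm$fn, cm$fp, cm$tp))
    expect_equal(unclass(swap_positive(sw)), unclass(cm))
    # counts conserve n and match a direct recount
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, n)
    expect_equal(cm$tp, sum(labs == "water" & preds == "water"))
    expect_equal(cm$fn, sum(labs == "water" & preds == "whale"))
  }
})

test_that("precision/recall match hand recomputation and flag zero denominators", {
  set.seed(12)
  for (i in 1:100) {
    cts <- sample(0:50, 4, replace = TRUE)
    cm <- confusion_from_counts(cts[1], cts[2], cts[3], cts[4])
    pr <- precision_recall(cm)
    if (cts[1] + cts[2] > 0)
      expect_equal(pr[["precision"]], cts[1] / (cts[1] + cts[2]))
    else expect_true(is.na(pr[["precision"]]))
    if (cts[1] + cts[3] > 0)
      expect_equal(pr[["recall"]], cts[1] / (cts[1] + cts[3]))
    else expect_true(is.na(pr[["recall"]]))
  }
})

test_that("F1 is the harmonic mean with its boundary identities", {
  expect_equal(f1(0.5, 0.5), 0.5)
  for (p in c(0.1, 0.37, 0.99)) expect_equal(f1(p, p), p)
  expect_true(is.na(f1(0, 0)))
  expect_true(is.na(f1(NA, 0.5)))
  # worked table values
  expect_equal(round(f1(0.996, 0.678), 3), 0.807)
  expect_equal(round(f1(0.995, 0.632), 3), 0.773)
  # F1 lies between precision and recall
  set.seed(13)
  for (i in 1:50) {
    p <- runif(1); r <- runif(1)
    v <- f1(p, r)
    expect_gte(v, min(p, r) - 1e-12)
    expect_lte(v, max(p, r) + 1e-12)
  }
})

test_that("whale-detection FPR uses the water denominator", {
  cm <- confusion_from_counts(tp = 1303, fp = 0, fn = 87, tn = 32)
  expect_equal(fpr_whale_detection(cm), 87 / 1390)
  expect_equal(round(fpr_whale_detection(cm), 4), 0.0626)
  expect_equal(fpr_whale_detection(confusion_from_counts(100, 5, 0, 7)), 0)
  expect_equal(fpr_whale_detection(confusion_from_counts(0, 5, 40, 7)), 1)
  expect_error(fpr_whale_detection(confusion_from_counts(0, 5, 0, 7)),
               "no water")
})

test_that("fold report summarizes per-fold metrics and keeps NA visible", {
  perfect <- replicate(10, confusion_from_counts(123, 0, 0, 2),
                       simplify = FALSE)
  rep10 <- fold_report(perfect)
  expect_equal(nrow(rep10), 13)
  expect_true(all(rep10$precision == 1))
  expect_equal(rep10$recall[rep10$fold == "min"],
               rep10$recall[rep10$fold == "max"])
  # degenerate all-water fold predicted all whale: precision undefined
  degen <- confusion_from_counts(0, 0, 50, 0)
  mixed <- fold_report(list(perfect[[1]], degen))
  expect_true(is.na(mixed$precision[2]))
  expect_false(is.na(mixed$precision[mixed$fold == "mean"]))
  # rows agree with independent recomputation
  set.seed(14)
  cms <- lapply(1:3, function(i)
    confusion_from_counts(sample(50:99, 1), sample(0:5, 1),
                          sample(0:9, 1), sample(1:9, 1)))
  tab <- fold_report(cms)
  for (i in 1:3) {
    expect_equal(tab$precision[i], cms[[i]]$tp / (cms[[i]]$tp + cms[[i]]$fp))
    expect_equal(tab$recall[i], cms[[i]]$tp / (cms[[i]]$tp + cms[[i]]$fn))
  }
})

test_that("learning-rate sweep table sorts, marks the best run, and validates", {
  one <- lr_sweep_report(data.frame(learning_rate = 6e-4, precision = 1,
                                    recall = 0.9))
  expect_true(one$best)
  runs <- data.frame(learning_rate = c(0.1, 1e-5, 6e-4),
                     precision = c(0.987, 1, 1),
                     recall = c(0.898, 0.722, 0.937))
  tab <- lr_sweep_report(runs)
  expect_equal(tab$learning_rate, sort(runs$learning_rate))
  f1s <- mapply(f1, runs$precision, runs$recall)
  expect_equal(tab$learning_rate[tab$best],
               runs$learning_rate[which.max(f1s)])
  expect_error(lr_sweep_report(rbind(runs, runs[1, ])), "duplicate")
  runs_bad <- runs; runs_bad$precision[2] <- NA
  expect_error(lr_sweep_report(runs_bad), "precision")
})

test_that("report rounding applies only to numeric columns", {
  r <- round_report(data.frame(model = "a", f1 = 0.96774), 3)
  expect_equal(r$f1, 0.968)
  expect_equal(r$model, "a")
})
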