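# Metrics and reports. The survey's convention treats correctly identified
# water as the positive outcome: precision is the share of model-classified
# water that truly is water, recall the share of true water the model
# found. The whale-detection false-positive rate (water tiles flagged as
# whale) is a separate convention and is reported side by side. Undefined
# metrics (zero denominators) surface as NA markers, never as silent zeros.

#' Two-class confusion matrix with an explicit positive class
#'
#' @param labels True labels, in `{"water", "whale"}`.
#' @param predictions Predicted labels, same length and symbols.
#' @param positive_class `"water"` (the survey convention) or `"whale"`.
#' @return Object of class `confusion_matrix`: list with `tp`, `fp`, `fn`,
#'   `tn`, `positive_class`, `n`.
#' @export
confusion <- function(labels, predictions, positive_class = "water") {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length (", length(labels),
         " vs ", length(predictions), ")")
  syms <- c("water", "whale")
  if (!all(labels %in% syms) || !all(predictions %in% syms))
    stop("labels must be 'water' or 'whale'")
  if (!positive_class %in% syms) stop("unknown positive_class")
  pos <- labels == positive_class
  ppos <- predictions == positive_class
  structure(list(tp = sum(pos & ppos), fp = sum(!pos & ppos),
                 fn = sum(pos & !ppos), tn = sum(!pos & !ppos),
                 positive_class = positive_class, n = length(labels)),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @param positive_class Declared positive class.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn, positive_class = "water") {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 positive_class = positive_class, n = tp + fp + fn + tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix (positive = %s): tp=%d fp=%d fn=%d tn=%d>\n",
              x$positive_class, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Swap the declared positive class
#'
#' Maps `(tp, fp, fn, tn)` to `(tn, fn, fp, tp)`; an involution.
#' @param cm A `confusion_matrix`.
#' @export
swap_positive <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  confusion_from_counts(cm$tn, cm$fn, cm$fp, cm$tp,
                        positive_class = setdiff(c("water", "whale"),
                                                 cm$positive_class))
}

#' Precision and recall
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`. A zero
#' denominator yields an explicit `NA` marker rather than 0.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  p <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  r <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  c(precision = p, recall = r)
}

#' F1 score
#'
#' Harmonic mean `2 P R / (P + R)`; `NA` when both are zero or either is
#' undefined.
#'
#' @param precision,recall Values in `[0, 1]` (or `NA`).
#' @return F1 in `[0, 1]` or `NA`.
#' @export
f1 <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Whale-detection false-positive rate
#'
#' The fraction of true water tiles the model flagged as whale -- the
#' quantity an image analyst cares about when false alarms are cheap to
#' discard. Note this is a different convention from the water-positive
#' precision/recall above (with water positive, these flagged tiles are the
#' false *negatives* of the water class). 87 water tiles flagged out of
#' 1,390 gives 0.0626.
#'
#' @param cm A `confusion_matrix` with `positive_class = "water"`.
#' @return Rate in `[0, 1]`.
#' @export
fpr_whale_detection <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$positive_class != "water") cm <- swap_positive(cm)
  n_water <- cm$tp + cm$fn
  if (n_water == 0) stop("no water tiles in the evaluated set")
  cm$fn / n_water
}

#' Full metric report for one confusion matrix
#'
#' @param cm A `confusion_matrix` (water positive; swapped if not).
#' @return One-row data frame: `n_water`, `n_whale`, `precision`, `recall`,
#'   `f1`, `fpr_whale_detection`.
#' @export
metric_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$positive_class != "water") cm <- swap_positive(cm)
  pr <- precision_recall(cm)
  data.frame(n_water = cm$tp + cm$fn, n_whale = cm$fp + cm$tn,
             precision = pr[["precision"]], recall = pr[["recall"]],
             f1 = f1(pr[["precision"]], pr[["recall"]]),
             fpr_whale_detection = if (cm$tp + cm$fn > 0)
               cm$fn / (cm$tp + cm$fn) else NA_real_)
}

#' Per-fold results table
#'
#' One row per fold (test-set class counts, precision, recall, F1) plus
#' `min` / `max` / `mean` summary rows. Undefined metrics propagate as `NA`
#' and are excluded from the summaries with a warning-free `na.rm`.
#'
#' @param cms List of water-positive `confusion_matrix`, one per fold.
#' @return Data frame with a `fold` column (`"1"`, ..., `"min"`, `"max"`,
#'   `"mean"`).
#' @export
fold_report <- function(cms) {
  stopifnot(length(cms) >= 1)
  rows <- lapply(seq_along(cms), function(i) {
    r <- metric_report(cms[[i]])
    cbind(data.frame(fold = as.character(i), stringsAsFactors = FALSE), r)
  })
  tab <- do.call(rbind, rows)
  num <- tab[, c("n_water", "n_whale", "precision", "recall", "f1",
                 "fpr_whale_detection")]
  summ <- function(f, nm) cbind(data.frame(fold = nm, stringsAsFactors = FALSE),
                                as.data.frame(lapply(num, f)))
  rbind(tab,
        summ(function(v) min(v, na.rm = TRUE), "min"),
        summ(function(v) max(v, na.rm = TRUE), "max"),
        summ(function(v) mean(v, na.rm = TRUE), "mean"))
}

#' Learning-rate sweep table
#'
#' @param runs Data frame (or list of lists) with columns `learning_rate`,
#'   `precision`, `recall` (and optionally `f1`; recomputed when absent).
#' @return Data frame sorted by learning rate with a logical `best` column
#'   marking the best-by-F1 run. Duplicate learning rates and missing
#'   precision fields are errors.
#' @export
lr_sweep_report <- function(runs) {
  if (!is.data.frame(runs)) runs <- do.call(rbind, lapply(runs, as.data.frame))
  stopifnot(nrow(runs) >= 1)
  need <- c("learning_rate", "precision", "recall")
  if (!all(need %in% names(runs)))
    stop("runs must provide ", paste(need, collapse = ", "))
  if (anyDuplicated(runs$learning_rate))
    stop("duplicate learning-rate entries")
  if (anyNA(runs$precision))
    stop("missing precision values in sweep")
  runs$f1 <- mapply(f1, runs$precision, runs$recall)
  runs <- runs[order(runs$learning_rate), , drop = FALSE]
  v <- runs$f1
  v[is.na(v)] <- -Inf
  runs$best <- seq_len(nrow(runs)) == which.max(v)
  rownames(runs) <- NULL
  runs
}

#' Round a report for display
#'
#' Tables are conventionally printed at 3 decimals; full precision is
#' retained in CSV exports.
#' @param report A data frame.
#' @param digits Decimal places.
#' @export
round_report <- function(report, digits = 3) {
  num <- vapply(report, is.numeric, TRUE)
  report[num] <- lapply(report[num], round, digits = digits)
  report
}
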