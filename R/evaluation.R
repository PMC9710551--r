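# Confusion-matrix scoring (accuracy, precision, recall, F1, ROC-AUC, MCC),
# cross-validation orchestration with per-fold mean +/- sd, and calibration
# diagnostics. P/LP is always the positive class. Undefined ratios (zero
# denominators) surface as NA, never as silent zeros.

#' Confusion counts with P/LP as the positive class
#'
#' @param y_true,y_pred equal-length label vectors over {PLP, BLB}.
#' @return object of class `confusion_counts`: list `tp, tn, fp, fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    sv_stop("savanno_schema", "label vectors differ in length (%d vs %d)",
            length(y_true), length(y_pred))
  }
  if (!all(c(y_true, y_pred) %in% c("PLP", "BLB"))) {
    sv_stop("savanno_schema", "labels must be PLP or BLB")
  }
  structure(list(tp = sum(y_true == "PLP" & y_pred == "PLP"),
                 tn = sum(y_true == "BLB" & y_pred == "BLB"),
                 fp = sum(y_true == "BLB" & y_pred == "PLP"),
                 fn = sum(y_true == "PLP" & y_pred == "BLB")),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Overall accuracy Q2 = (TP+TN)/total, precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = harmonic mean of precision and recall, and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). All stored
#' as fractions; rendering as percents is a formatting concern.
#'
#' @param counts a `confusion_counts` (or list with tp/tn/fp/fn).
#' @return object of class `metrics_report`: list with `q2, precision,
#'   recall, f1, mcc` (NA when undefined) and the counts.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total < 1) sv_stop("savanno_schema", "empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  q2 <- ratio(tp + tn, total)
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  structure(list(q2 = q2, precision = precision, recall = recall, f1 = f1,
                 mcc = mcc, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", 100 * v)
  cat(sprintf("<metrics_report> Q2 %s%% | precision %s%% | recall %s%% | F1 %s%% | MCC %s\n",
              pct(x$q2), pct(x$precision), pct(x$recall), pct(x$f1),
              if (is.na(x$mcc)) "NA" else sprintf("%.3f", x$mcc)))
  if (!is.null(x$auc)) cat(sprintf("  ROC-AUC %s%%\n", pct(x$auc)))
  invisible(x)
}

#' ROC area under the curve
#'
#' Tie-corrected Mann-Whitney rank statistic: the probability that a random
#' P/LP score exceeds a random B/LB score, counting ties as one half.
#'
#' @param scores numeric decision scores (higher = more pathogenic).
#' @param y_true labels over {PLP, BLB}; both classes must be present
#'   (otherwise NA with a warning).
#' @return AUC in [0, 1], or NA when undefined.
#' @export
roc_auc <- function(scores, y_true) {
  y_true <- as.character(y_true)
  stopifnot(length(scores) == length(y_true))
  npos <- sum(y_true == "PLP"); nneg <- sum(y_true == "BLB")
  if (npos == 0 || nneg == 0) {
    sv_log("WARN", "roc_auc: single-class input, AUC undefined")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == "PLP"]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Cross-validated evaluation of the pipeline
#'
#' For every fold: train the PCA+SVM stage on the remaining folds
#' (projection refitted each time), score the held-out fold, and compute
#' the metrics. Reports per-fold values plus their unweighted mean and
#' sample standard deviation. A fold whose labels are single-class has its
#' undefined metrics flagged NA and is excluded from the mean with a
#' warning.
#'
#' @param X feature matrix.
#' @param y labels (`PLP`/`BLB`).
#' @param folds per-row fold ids (>= 2 distinct values).
#' @param config a [pipeline_config()].
#' @return object of class `cv_report`: list with `per_fold` (data frame),
#'   `mean`, `sd` (named numeric vectors over the metric columns) and
#'   `pooled` predictions.
#' @export
cross_validate <- function(X, y, folds, config = pipeline_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  fold_ids <- sort(unique(as.character(folds)))
  if (length(fold_ids) < 2L) sv_stop("savanno_config", "cross-validation needs >= 2 folds")
  folds <- as.character(folds)
  rows <- list()
  pooled <- data.frame(fold = character(0), y = character(0),
                       score = numeric(0), pred = character(0),
                       stringsAsFactors = FALSE)
  for (f in fold_ids) {
    te <- folds == f
    if (length(unique(y[!te])) < 2L) {
      sv_log("WARN", "fold %s: training complement is single-class, fold skipped", f)
      next
    }
    stage <- fit_stage(X[!te, , drop = FALSE], y[!te], config)
    sc <- stage_scores(stage, X[te, , drop = FALSE])
    pred <- ifelse(sc >= config$decision_threshold, "PLP", "BLB")
    single <- length(unique(y[te])) < 2L
    if (single) {
      sv_log("WARN", "fold %s holds a single class; its undefined metrics are flagged", f)
    }
    m <- classification_metrics(confusion_counts(y[te], pred))
    auc <- roc_auc(sc, y[te])
    rows[[f]] <- data.frame(fold = f, n = sum(te),
                            q2 = m$q2, precision = m$precision, recall = m$recall,
                            f1 = m$f1, auc = auc, mcc = m$mcc,
                            stringsAsFactors = FALSE)
    pooled <- rbind(pooled, data.frame(fold = f, y = y[te], score = sc,
                                       pred = pred, stringsAsFactors = FALSE))
  }
  per_fold <- do.call(rbind, rows)
  rownames(per_fold) <- NULL
  metric_cols <- c("q2", "precision", "recall", "f1", "auc", "mcc")
  mean_v <- vapply(metric_cols, function(cc) mean(per_fold[[cc]], na.rm = TRUE), numeric(1))
  sd_v <- vapply(metric_cols, function(cc) stats::sd(per_fold[[cc]], na.rm = TRUE), numeric(1))
  structure(list(per_fold = per_fold, mean = mean_v, sd = sd_v, pooled = pooled),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds\n", nrow(x$per_fold)))
  f <- function(m) sprintf("%.1f (+/-%.1f)", 100 * x$mean[[m]], 100 * x$sd[[m]])
  cat(sprintf("  Q2 %s | precision %s | recall %s | F1 %s | AUC %s | MCC %.2f (+/-%.2f)\n",
              f("q2"), f("precision"), f("recall"), f("f1"), f("auc"),
              x$mean[["mcc"]], x$sd[["mcc"]]))
  invisible(x)
}

#' Histogram of predicted pathogenicity probabilities
#'
#' Bins probabilities over [0, 1] and reports the side counts used in
#' survey-style summaries: predicted P/LP (probability >= 0.5), predicted
#' B/LB (< 0.5), and how many on each side reach reliability index >= 6.
#'
#' @param predictions data frame from [predict_pipeline()] (needs columns
#'   `probability` and `reliability_index`).
#' @param bins number of equal-width bins (default 20).
#' @return list with `breaks`, `counts`, `n_plp`, `n_blb`, `n_plp_ri6`,
#'   `n_blb_ri6`.
#' @export
probability_histogram <- function(predictions, bins = 20L) {
  p <- predictions$probability
  if (any(p < 0 | p > 1)) sv_stop("savanno_schema", "probabilities outside [0, 1]")
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(p, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(idx, nbins = bins)
  ri <- predictions$reliability_index
  list(breaks = breaks, counts = counts,
       n_plp = sum(p >= 0.5), n_blb = sum(p < 0.5),
       n_plp_ri6 = sum(p >= 0.5 & ri >= 6L),
       n_blb_ri6 = sum(p < 0.5 & ri >= 6L))
}

#' Decile reliability diagram gap
#'
#' Splits predictions into probability deciles and returns the mean
#' absolute gap between the mean predicted probability and the empirical
#' P/LP fraction per occupied decile — the testable restatement of "close
#' to perfectly calibrated".
#'
#' @param probability calibrated probabilities.
#' @param y_true labels over {PLP, BLB}.
#' @return mean absolute calibration gap across occupied deciles.
#' @export
calibration_gap <- function(probability, y_true) {
  stopifnot(length(probability) == length(y_true))
  bin <- pmin(pmax(ceiling(probability * 10), 1L), 10L)
  gaps <- vapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    abs(mean(probability[sel]) - mean(y_true[sel] == "PLP"))
  }, numeric(1))
  mean(gaps)
}

#' Render a metrics report as a table row (percent scale)
#'
#' @param report a `metrics_report` or `cv_report`.
#' @return one-row data frame with percents to one decimal and MCC to two.
#' @export
format_metrics <- function(report) {
  if (inherits(report, "cv_report")) {
    f <- function(m) sprintf("%.1f (%.1f)", 100 * report$mean[[m]], 100 * report$sd[[m]])
    return(data.frame(Q2 = f("q2"), Precision = f("precision"), Recall = f("recall"),
                      F1 = f("f1"), ROC_AUC = f("auc"),
                      MCC = sprintf("%.2f (%.2f)", report$mean[["mcc"]], report$sd[["mcc"]]),
                      stringsAsFactors = FALSE))
  }
  pct <- function(v) if (is.na(v)) NA_character_ else sprintf("%.1f", 100 * v)
  data.frame(Q2 = pct(report$q2), Precision = pct(report$precision),
             Recall = pct(report$recall), F1 = pct(report$f1),
             ROC_AUC = if (is.null(report$auc)) NA_character_ else pct(report$auc),
             MCC = if (is.na(report$mcc)) NA_character_ else sprintf("%.2f", report$mcc),
             stringsAsFactors = FALSE)
}
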