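#' Precision, recall and F1 from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 the harmonic mean of
#' the two. A ratio with a zero denominator is reported as NA (undefined),
#' not as 0; F1 is 0 when precision and recall are both defined and both 0.
#'
#' @param tp,fp,fn,tn confusion counts (tn optional, for bookkeeping).
#' @return a list of class `metrics_report`: `precision`, `recall`, `f1`
#'   (fractions in 0..1), and the counts.
#' @export
confusion_metrics <- function(tp, fp, fn, tn = NA_real_) {
  if (any(c(tp, fp, fn) < 0, na.rm = TRUE))
    stop("confusion_metrics: counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.2f%%  recall %.2f%%  F1 %.2f%%  (TP %s FP %s FN %s)\n",
              100 * x$precision, 100 * x$recall, 100 * x$f1,
              format(x$tp, big.mark = ","), format(x$fp, big.mark = ","),
              format(x$fn, big.mark = ",")))
  invisible(x)
}

#' Confusion counts from aligned prediction and label vectors
#'
#' @param pred,label logical (or 0/1) vectors.
#' @return a `metrics_report`.
#' @export
prediction_metrics <- function(pred, label) {
  pred <- as.logical(pred); label <- as.logical(label)
  if (length(pred) != length(label))
    stop("prediction_metrics: length mismatch")
  confusion_metrics(tp = sum(pred & label), fp = sum(pred & !label),
                    fn = sum(!pred & label), tn = sum(!pred & !label))
}

#' Carry-forward baseline prediction
#'
#' Predicts the next-visit label as the positivity of the last input visit
#' (the hypertension rule applied to its blood pressures).
#'
#' @param samples a samples data.frame from [assemble_dataset()] (uses
#'   `last_sbp`, `last_dbp`).
#' @return logical predictions.
#' @export
baseline_predict <- function(samples) {
  if (any(samples$n_input < 1)) stop("baseline_predict: sample without input")
  label_visit(samples$last_sbp, samples$last_dbp)
}

#' Metrics stratified by input-visit count and past-hypertension status
#'
#' Reports overall metrics plus per-stratum metrics for the number of
#' input visits (1..max) and for whether any input visit met the
#' hypertension rule in the past. Empty strata are omitted.
#'
#' @param samples samples data.frame aligned with `pred`.
#' @param pred logical predictions.
#' @return a list: `overall` (metrics_report), `by_visit_count` (named list
#'   of metrics per input count), `by_past` (metrics for
#'   `past_positive` and `past_negative`).
#' @export
stratified_report <- function(samples, pred) {
  if (length(pred) != nrow(samples))
    stop("stratified_report: predictions not aligned with samples")
  lab <- samples$label
  by_count <- list()
  for (kk in sort(unique(samples$n_input))) {
    i <- samples$n_input == kk
    by_count[[as.character(kk)]] <- prediction_metrics(pred[i], lab[i])
  }
  by_past <- list()
  for (p in c(TRUE, FALSE)) {
    i <- samples$past_positive == p
    if (!any(i)) next
    by_past[[if (p) "past_positive" else "past_negative"]] <-
      prediction_metrics(pred[i], lab[i])
  }
  list(overall = prediction_metrics(pred, lab),
       by_visit_count = by_count, by_past = by_past)
}

#' Area under the ROC curve
#'
#' @param scores continuous scores (higher = more positive).
#' @param labels 0/1 (or logical) true labels.
#' @return the AUROC as a fraction.
#' @export
auroc <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(as.integer(labels), scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Per-fold ROC AUC on a test set
#'
#' @param ensemble an `nv_ensemble`.
#' @param x encoded test features.
#' @param y 0/1 labels.
#' @return numeric vector of AUROC per fold model.
#' @export
auroc_by_fold <- function(ensemble, x, y) {
  pr <- predict_ensemble(ensemble, x)$prob
  vapply(seq_len(ncol(pr)), function(f) auroc(pr[, f], y), 1)
}

#' Aggregate feature importance across visit slots and folds
#'
#' Sums each factor's importance over its `n1` visit-slot columns within a
#' fold, averages across folds, and normalizes to shares. Presence
#' indicator columns are aggregated under `"presence"`. Boosted models use
#' gain importance; random forests use mean decrease in Gini.
#'
#' @param ensemble an `nv_ensemble`.
#' @return a data.frame of class `importance_table` with `factor`,
#'   `importance` (shares summing to 1), sorted descending.
#' @export
aggregate_importance <- function(ensemble) {
  base_factor <- function(cols) {
    out <- ifelse(grepl("^present\\.v\\d+$", cols), "presence",
                  sub("^v\\d+\\.", "", cols))
    bad <- !grepl("^present\\.v\\d+$|^v\\d+\\.", cols)
    if (any(bad))
      stop("aggregate_importance: columns not mappable to a factor: ",
           paste(cols[bad], collapse = ", "))
    out
  }
  factors <- unique(base_factor(ensemble$feature_names))
  acc <- matrix(0, length(ensemble$folds), length(factors),
                dimnames = list(NULL, factors))
  for (f in seq_along(ensemble$folds)) {
    fm <- ensemble$folds[[f]]
    if (fm$model_type %in% c("xgb", "lgbm")) {
      imp <- xgboost::xgb.importance(model = fm$model)
      cols <- imp$Feature
      val <- imp$Gain
    } else {
      mi <- randomForest::importance(fm$model)
      cols <- rownames(mi)
      val <- mi[, 1]
    }
    bf <- base_factor(cols)
    agg <- tapply(val, bf, sum)
    acc[f, names(agg)] <- agg
  }
  share <- colMeans(acc)
  share <- share / sum(share)
  out <- data.frame(factor = names(share), importance = as.numeric(share),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Matthews correlation coefficient between two binary vectors
#'
#' @param a,b logical (or 0/1) vectors.
#' @return the MCC (NA when a marginal is degenerate).
#' @export
mcc <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("mcc: length mismatch")
  tp <- as.double(sum(a & b)); tn <- as.double(sum(!a & !b))
  fp <- as.double(sum(!a & b)); fn <- as.double(sum(a & !b))
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

#' One-tailed paired comparison of two classifiers' correctness
#'
#' Applies a one-tailed paired t-test to the per-sample correctness
#' indicators of method A versus method B (alternative: A more often
#' correct). A McNemar-type exact test would be the conventional choice
#' for paired binary outcomes; the paired t is retained as this pipeline's
#' stated comparison and is asymptotically equivalent here.
#'
#' @param correct_a,correct_b logical vectors: whether each method was
#'   correct on each test sample (aligned).
#' @return a list: `t`, `df`, `p_value` (one-tailed, A > B), `mean_diff`.
#' @export
compare_methods <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b))
    stop("compare_methods: length mismatch")
  a <- as.numeric(correct_a); b <- as.numeric(correct_b)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    # degenerate contrasts: identical methods give t = 0 (p = 0.5); a
    # constant nonzero difference gives t = +/-Inf
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (t_stat == 0) 0.5 else if (t_stat > 0) 0 else 1
    return(list(t = t_stat, df = n - 1, p_value = p, mean_diff = mean(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate))
}
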