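#!/usr/bin/env Rscript
# Evaluate the ensemble on the held-out test samples against the
# carry-forward baseline (predict the next visit with the positivity of
# the last observed visit): overall precision/recall/F1, per-fold AUROC,
# strata by input-visit count and by past-hypertension status, a paired
# one-tailed comparison of per-sample correctness, and fold-averaged
# feature importance.

library(nextvisit)

st <- readRDS("scratch/analysis/model.rds")
schema <- feature_schema()
test <- encode_dataset(st$ds, schema, n1 = 5, split = "test")

pred <- predict_ensemble(st$ensemble, test$x)
ours <- prediction_metrics(pred$final, test$y == 1)
bl <- baseline_predict(test$samples)
base <- prediction_metrics(bl, test$y == 1)

cat("ensemble: "); print(ours)
cat("baseline: "); print(base)
auc <- auroc_by_fold(st$ensemble, test$x, test$y)
cat(sprintf("per-fold AUROC: %.2f%% to %.2f%%\n",
            100 * min(auc), 100 * max(auc)))

cmp <- compare_methods(pred$final == (test$y == 1), bl == (test$y == 1))
cat(sprintf("paired one-tailed t-test, ensemble vs baseline: t = %.2f, p = %.3g\n",
            cmp$t, cmp$p_value))

strat <- stratified_report(test$samples, pred$final)
strat_base <- stratified_report(test$samples, bl)
cat("no-past-hypertension stratum, ensemble: ")
print(strat$by_past$past_negative)
cat("no-past-hypertension stratum, baseline: ")
print(strat_base$by_past$past_negative)

imp <- aggregate_importance(st$ensemble)
write.csv(transform(head(imp, 20), importance = round(importance, 4)),
          "results/importance_top20.csv", row.names = FALSE)
cat("top 5 factors by fold-averaged importance share:\n")
print(head(imp, 5))

flat <- function(m) list(precision = m$precision, recall = m$recall,
                         f1 = m$f1)
jsonlite::write_json(list(
  ensemble = flat(ours), baseline = flat(base),
  auroc = list(min = min(auc), max = max(auc)),
  t_test = cmp[c("t", "p_value")],
  by_visit_count = lapply(strat$by_visit_count, flat),
  by_past = lapply(strat$by_past, flat)),
  "results/evaluation.json", auto_unbox = TRUE, digits = NA)
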