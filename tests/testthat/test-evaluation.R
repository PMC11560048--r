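test_that("confusion metrics reproduce the published confusion tables", {
  ours <- confusion_metrics(tp = 19595, fp = 8564, fn = 5559, tn = 41084)
  expect_equal(round(100 * ours$precision, 2), 69.59)
  expect_equal(round(100 * ours$recall, 2), 77.90)
  expect_equal(round(100 * ours$f1, 2), 73.51)

  base <- confusion_metrics(tp = 17464, fp = 6799, fn = 7690, tn = 42849)
  expect_equal(round(100 * base$precision, 2), 71.98)
  expect_equal(round(100 * base$recall, 2), 69.43)
  expect_equal(round(100 * base$f1, 2), 70.68)

  fram <- confusion_metrics(tp = 18611, fp = 8884, fn = 6543, tn = 40764)
  expect_equal(round(100 * fram$precision, 2), 67.69)
  expect_equal(round(100 * fram$recall, 2), 73.99)
  expect_equal(round(100 * fram$f1, 2), 70.70)
})

test_that("degenerate confusion tables are handled as defined", {
  perfect <- confusion_metrics(tp = 10, fp = 0, fn = 0)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  undef <- confusion_metrics(tp = 0, fp = 0, fn = 5)
  expect_true(is.na(undef$precision))
  expect_equal(undef$recall, 0)
  expect_true(is.na(undef$f1))

  allwrong <- confusion_metrics(tp = 0, fp = 3, fn = 5)
  expect_equal(allwrong$f1, 0)

  expect_error(confusion_metrics(-1, 0, 0), "non-negative")
})

test_that("F1 is the harmonic mean and is bracketed by precision and recall", {
  set.seed(6)
  for (trial in 1:50) {
    m <- confusion_metrics(tp = sample(1:100, 1), fp = sample(1:100, 1),
                           fn = sample(1:100, 1))
    expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall), tolerance = 1e-12)
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("carry-forward baseline applies the label rule to the last input visit", {
  s <- data.frame(n_input = c(1, 2, 3),
                  last_sbp = c(135, 120, 120),
                  last_dbp = c(70, 75, 80))
  expect_equal(baseline_predict(s), c(TRUE, FALSE, TRUE))
})

test_that("stratified reports recompute metrics on each subset", {
  coh <- shared_cohort()
  ds <- assemble_dataset(coh, window_config())
  te <- ds$samples[ds$samples$split == "test", ]
  bl <- baseline_predict(te)
  rep <- stratified_report(te, bl)

  # the baseline can never find a positive in the no-past-positive stratum
  expect_equal(rep$by_past$past_negative$recall, 0)

  # per-stratum numbers equal direct recomputation on the subset
  i <- te$past_positive
  direct <- prediction_metrics(bl[i], te$label[i])
  expect_equal(rep$by_past$past_positive$precision, direct$precision)
  expect_equal(rep$by_past$past_positive$f1, direct$f1)

  j <- te$n_input == 1
  direct1 <- prediction_metrics(bl[j], te$label[j])
  expect_equal(rep$by_visit_count[["1"]]$recall, direct1$recall)

  # single-visit-only samples collapse the visit-count strata to the overall
  one <- te[j, ]
  rep1 <- stratified_report(one, bl[j])
  expect_equal(rep1$by_visit_count[["1"]]$f1, rep1$overall$f1)
})

test_that("AUROC of random scores on balanced labels is about one half", {
  set.seed(33)
  n <- 10000
  labels <- rep(0:1, each = n / 2)
  scores <- runif(n)
  expect_equal(auroc(scores, labels), 0.5, tolerance = 0.02)
  # and a perfect ranking scores 1
  expect_equal(auroc(labels + 0, labels), 1)
})

test_that("importance aggregation maps window columns to base factors and normalizes", {
  set.seed(14)
  n <- 400
  # only one factor's columns carry signal; the others are constant
  informative <- rnorm(n)
  x <- cbind(informative, 1, 1)
  colnames(x) <- c("v5.map", "v4.map", "present.v5")
  y <- as.integer(informative > 0)
  ens <- train_ensemble(x, y, 70 + informative, rnorm(n, 120),
                        nrounds_max = 60, seed = 6)
  imp <- aggregate_importance(ens)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$factor[1], "map")
  expect_equal(imp$importance[1], 1, tolerance = 1e-9)

  ens_bad <- ens
  ens_bad$feature_names <- c("v5.map", "nonsense", "present.v5")
  expect_error(aggregate_importance(ens_bad), "not mappable")
})

test_that("paired one-tailed comparison and MCC behave on degenerate and random inputs", {
  a <- c(TRUE, FALSE, TRUE, TRUE)
  cmp_same <- compare_methods(a, a)
  expect_equal(cmp_same$t, 0)
  expect_equal(mcc(a, a), 1)

  cmp_dom <- compare_methods(rep(TRUE, 50), rep(FALSE, 50))
  expect_equal(cmp_dom$p_value, 0)
  expect_equal(cmp_dom$t, Inf)

  # textbook paired-t oracle on random correctness vectors
  set.seed(55)
  ca <- rbinom(1000, 1, 0.7)
  cb <- rbinom(1000, 1, 0.65)
  got <- compare_methods(ca, cb)
  d <- ca - cb
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$p_value, pt(t_manual, length(d) - 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # MCC equals the phi coefficient computed from the contingency table
  x <- rbinom(300, 1, 0.5); y <- rbinom(300, 1, 0.5)
  tab <- table(factor(x, 0:1), factor(y, 0:1))
  phi <- (tab[2, 2] * tab[1, 1] - tab[1, 2] * tab[2, 1]) /
    sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
  expect_equal(mcc(x, y), unname(phi), tolerance = 1e-12)

  expect_error(compare_methods(a, a[1:2]), "length mismatch")
})
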