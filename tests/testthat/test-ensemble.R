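# Brute-force F1 maximization over every achievable prediction set: the
# oracle thresholds at each distinct probability (and above the maximum)
# and takes the best F1 achieved.
bf_best_f1 <- function(prob, labels) {
  cands <- c(sort(unique(prob)), max(prob) + 1)
  best <- 0
  for (t in cands) {
    pred <- prob >= t
    tp <- sum(pred & labels == 1)
    if (tp == 0) next
    p <- tp / sum(pred); r <- tp / sum(labels == 1)
    best <- max(best, 2 * p * r / (p + r))
  }
  best
}

achieved_f1 <- function(th, prob, labels) {
  pred <- prob >= th
  tp <- sum(pred & labels == 1)
  if (tp == 0) return(0)
  p <- tp / sum(pred); r <- tp / sum(labels == 1)
  2 * p * r / (p + r)
}

test_that("sorted mod-5 assignment interleaves and balances folds", {
  dbp <- c(95, 60, 75, 80, 62, 88, 70, 66, 91, 73)
  sbp <- rep(120, 10)
  f <- assign_folds(dbp, sbp, k = 5)
  ord <- order(dbp)
  expect_equal(f[ord], rep(1:5, 2))
  expect_true(all(table(f) == 2))

  # ties everywhere: sizes still differ by at most 1
  f2 <- assign_folds(rep(80, 13), rep(130, 13), k = 5)
  expect_lte(diff(range(table(f2))), 1)

  # interleaving balances the outcome distribution across folds
  set.seed(2)
  dbp3 <- rnorm(500, 75, 10); sbp3 <- rnorm(500, 120, 12)
  f3 <- assign_folds(dbp3, sbp3)
  fold_means <- tapply(dbp3, f3, mean)
  expect_lt(diff(range(fold_means)), sd(dbp3))
  expect_lte(diff(range(table(f3))), 1)
})

test_that("threshold tuning finds the exact F1 optimum with ties toward larger thresholds", {
  th <- tune_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(th, 0.5)

  expect_error(tune_threshold(c(0.2, 0.8), c(1, 1)), "single class")

  # perfect anti-predictor: best move is predicting everything positive
  p <- c(0.9, 0.8, 0.2, 0.1); y <- c(0, 0, 1, 1)
  th2 <- tune_threshold(p, y)
  expect_lt(th2, min(p))
  expect_equal(achieved_f1(th2, p, y), 2 / 3, tolerance = 1e-12)
})

test_that("threshold tuning equals the brute-force scan on 200 random instances", {
  set.seed(19)
  for (trial in 1:200) {
    n <- sample(5:40, 1)
    p <- round(runif(n), sample(1:3, 1))  # induce ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    th <- tune_threshold(p, y)
    expect_equal(achieved_f1(th, p, y), bf_best_f1(p, y), tolerance = 1e-12)
  }
})

test_that("fold fitting selects capacity by validation loss on separable toy data", {
  set.seed(8)
  n <- 400
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- as.integer(x[, "a"] + x[, "b"] > 0)
  tr <- seq_len(300); va <- 301:400
  fm <- fit_fold(x[tr, ], y[tr], x[va, ], y[va], model_type = "xgb",
                 nrounds_max = 1000, seed = 5)
  expect_lt(fm$best_val_loss, 0.1)
  expect_true(fm$th > 0 && fm$th < 1)
  expect_lte(fm$capacity, 1000)

  # kept capacity is at least as good as the full-capacity model
  p_full <- predict(fm$model, x[va, ])
  loss_full <- -mean(y[va] * log(pmax(p_full, 1e-12)) +
                     (1 - y[va]) * log(pmax(1 - p_full, 1e-12)))
  expect_lte(fm$best_val_loss, loss_full + 1e-10)

  # determinism under a fixed seed
  fm2 <- fit_fold(x[tr, ], y[tr], x[va, ], y[va], model_type = "xgb",
                  nrounds_max = 1000, seed = 5)
  expect_equal(fm$capacity, fm2$capacity)
  expect_equal(fm$th, fm2$th)

  expect_error(fit_fold(x[tr, ], rep(1L, 300), x[va, ], y[va]),
               "single class")
})

test_that("leaf-wise and random-forest fold models also separate toy data", {
  set.seed(12)
  n <- 240
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- as.integer(x[, "a"] > 0.2 * x[, "b"])
  tr <- seq_len(180); va <- 181:240
  lg <- fit_fold(x[tr, ], y[tr], x[va, ], y[va], model_type = "lgbm",
                 nrounds_max = 600, seed = 3)
  expect_lt(lg$best_val_loss, 0.25)
  rf <- fit_fold(x[tr, ], y[tr], x[va, ], y[va], model_type = "rf",
                 rf_grid = c(50, 100), seed = 3)
  expect_lt(rf$best_val_loss, 0.35)
  expect_true(rf$capacity %in% c(50, 100))
})

test_that("ensemble voting respects per-fold thresholds and majority rule", {
  set.seed(40)
  n <- 500
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  latent <- x[, "a"] + 0.5 * x[, "b"]
  y <- as.integer(latent + rnorm(n, 0, 0.7) > 0)
  dbp <- 75 + 8 * latent + rnorm(n)
  sbp <- 120 + 10 * latent + rnorm(n)
  ens <- train_ensemble(x, y, dbp, sbp, model_type = "xgb",
                        nrounds_max = 150, seed = 9)
  # folds partition the training set with sizes within 1
  expect_lte(diff(range(table(ens$fold_of))), 1)
  expect_equal(sort(unique(ens$fold_of)), 1:5)

  pr <- predict_ensemble(ens, x)
  ths <- vapply(ens$folds, `[[`, 1, "th")
  expect_equal(pr$votes, sweep(pr$prob, 2, ths, `>=`))
  expect_equal(pr$final, rowSums(pr$votes) >= 3)

  # vote-order permutation invariance
  ens2 <- ens
  perm <- c(3, 5, 1, 4, 2)
  ens2$folds <- ens$folds[perm]
  expect_equal(predict_ensemble(ens2, x)$final, pr$final)

  ens3 <- ens
  ens3$folds[2] <- list(NULL)
  expect_error(predict_ensemble(ens3, x[1:3, , drop = FALSE]))

  # training twice with the same seed reproduces capacities and thresholds
  ens4 <- train_ensemble(x, y, dbp, sbp, model_type = "xgb",
                         nrounds_max = 150, seed = 9)
  expect_equal(vapply(ens4$folds, `[[`, 1L, "capacity"),
               vapply(ens$folds, `[[`, 1L, "capacity"))
  expect_equal(vapply(ens4$folds, `[[`, 1, "th"), ths)
})

test_that("ensemble manifest serializes fold capacities and thresholds", {
  set.seed(41)
  x <- cbind(a = rnorm(120), b = rnorm(120))
  y <- as.integer(x[, 1] > 0)
  ens <- train_ensemble(x, y, 70 + x[, 1], 120 + x[, 2],
                        nrounds_max = 40, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble_manifest(ens, path)
  man <- jsonlite::read_json(path)
  expect_equal(man$model_type, "xgb")
  expect_length(man$folds, 5)
  expect_equal(man$folds[[1]]$th, ens$folds[[1]]$th)
})
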