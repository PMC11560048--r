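#' Sorted-split fold assignment
#'
#' Training samples are sorted by the output visit's raw diastolic blood
#' pressure (primary key) and systolic blood pressure (secondary key) with
#' original index as the final tiebreaker, then assigned to folds by the
#' sorted index modulo `k`. Interleaving a sorted sequence balances the
#' outcome blood-pressure distribution across folds.
#'
#' @param out_dbp,out_sbp output-visit blood pressures per training sample.
#' @param k number of folds.
#' @return integer fold index in 1..k per sample (original order).
#' @export
assign_folds <- function(out_dbp, out_sbp, k = 5) {
  n <- length(out_dbp)
  if (n == 0) stop("assign_folds: empty training set")
  ord <- order(out_dbp, out_sbp, seq_len(n))
  fold <- integer(n)
  fold[ord] <- (seq_len(n) - 1L) %% k + 1L
  fold
}

#' F1-optimal probability threshold on a validation set
#'
#' Scans every achievable confusion table: candidate thresholds are the
#' midpoints between consecutive sorted unique probabilities, plus one
#' below the minimum (predict everything positive) and one above the
#' maximum. A prediction is positive when probability >= threshold. Ties in
#' F1 are broken toward the larger threshold.
#'
#' @param prob predicted probabilities.
#' @param labels 0/1 (or logical) true labels; both classes must be
#'   present.
#' @return the selected threshold.
#' @export
tune_threshold <- function(prob, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("tune_threshold: validation labels contain a single class")
  u <- sort(unique(prob))
  cands <- c(u[1] / 2,
             if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
             (u[length(u)] + 1) / 2)
  npos <- sum(labels)
  f1 <- vapply(cands, function(t) {
    pred <- prob >= t
    tp <- sum(pred & labels == 1)
    if (tp == 0) return(0)
    p <- tp / sum(pred)
    r <- tp / npos
    2 * p * r / (p + r)
  }, 1)
  cands[max(which(f1 == max(f1)))]
}

binary_xent <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit one cross-validation fold
#'
#' Trains a tree classifier on the fold's training subset, selects the
#' capacity (boosting rounds or forest size) minimizing validation
#' cross-entropy, and tunes the F1-optimal decision threshold on the
#' validation subset.
#'
#' Model types: `"xgb"` is a depth-wise gradient-boosted tree (depth 5);
#' `"lgbm"` is a leaf-wise-grown gradient-boosted tree (20 leaves, depth
#' cap 15, histogram splits); `"rf"` is a random forest (depth cap via
#' node size default, grid search over forest sizes). Boosted types use
#' learning rate 0.01 and train up to `nrounds_max` rounds, keeping the
#' round with the best validation loss.
#'
#' @param x_train,y_train training subset (matrix, 0/1 labels; both classes
#'   required).
#' @param x_val,y_val validation subset.
#' @param model_type "xgb", "lgbm" or "rf".
#' @param nrounds_max maximal boosting rounds.
#' @param rf_grid forest sizes searched for "rf".
#' @param seed integer seed for the learner.
#' @param fold_index stored for bookkeeping.
#' @return a list of class `fold_model`: `model`, `model_type`, `capacity`,
#'   `th`, `best_val_loss`, `fold_index`.
#' @export
fit_fold <- function(x_train, y_train, x_val, y_val,
                     model_type = c("xgb", "lgbm", "rf"),
                     nrounds_max = 1000,
                     rf_grid = c(seq(100, 500, by = 100),
                                 seq(600, 1000, by = 50)),
                     seed = 1L, fold_index = NA_integer_) {
  model_type <- match.arg(model_type)
  y_train <- as.integer(y_train)
  y_val <- as.integer(y_val)
  if (length(unique(y_train)) < 2)
    stop("fit_fold: training subset contains a single class; ",
         "cannot fit a classifier (fold ", fold_index, ")")
  if (length(unique(y_val)) < 2)
    stop("fit_fold: validation subset contains a single class (fold ",
         fold_index, ")")

  if (model_type %in% c("xgb", "lgbm")) {
    params <- list(objective = "binary:logistic", eta = 0.01,
                   eval_metric = "logloss", nthread = 1,
                   seed = as.integer(seed))
    if (model_type == "xgb") {
      params$max_depth <- 5
    } else {
      params$max_depth <- 15
      params$max_leaves <- 20
      params$grow_policy <- "lossguide"
      params$tree_method <- "hist"
    }
    dtr <- xgboost::xgb.DMatrix(x_train, label = y_train)
    dva <- xgboost::xgb.DMatrix(x_val, label = y_val)
    bst <- xgboost::xgb.train(params = params, data = dtr,
                              nrounds = nrounds_max,
                              evals = list(val = dva), verbose = 0)
    el <- attributes(bst)$evaluation_log
    capacity <- which.min(el$val_logloss)
    best_loss <- min(el$val_logloss)
    model <- bst
    p_val <- predict(bst, x_val, iterationrange = c(1, capacity))
  } else {
    best_loss <- Inf
    model <- NULL
    capacity <- NA_integer_
    for (g in rf_grid) {
      set.seed(seed + g)
      rf <- randomForest::randomForest(
        x = x_train, y = factor(y_train, levels = c(0, 1)),
        ntree = g, maxnodes = min(2L^15L, nrow(x_train)))  # depth-15 cap
      p <- predict(rf, x_val, type = "prob")[, "1"]
      loss <- binary_xent(y_val, p)
      if (loss < best_loss) {
        best_loss <- loss
        model <- rf
        capacity <- g
      }
    }
    p_val <- predict(model, x_val, type = "prob")[, "1"]
  }

  structure(list(model = model, model_type = model_type,
                 capacity = as.integer(capacity),
                 th = tune_threshold(p_val, y_val),
                 best_val_loss = best_loss,
                 fold_index = fold_index),
            class = "fold_model")
}

fold_model_prob <- function(fm, x) {
  if (fm$model_type %in% c("xgb", "lgbm")) {
    predict(fm$model, x, iterationrange = c(1, fm$capacity))
  } else {
    predict(fm$model, x, type = "prob")[, "1"]
  }
}

#' Train the sorted-split voting ensemble
#'
#' Assigns training samples to `k` folds by the sorted-split rule, fits one
#' model per fold (validated on the held-out fold, trained on the rest),
#' and stores the per-fold F1-optimal thresholds used at voting time.
#'
#' @param x training feature matrix (encoded windows).
#' @param y 0/1 labels.
#' @param out_dbp,out_sbp output-visit blood pressures (fold sorting keys).
#' @param model_type "xgb" (default, the best-validation-loss choice),
#'   "lgbm" or "rf".
#' @param k number of folds.
#' @param nrounds_max,rf_grid capacity search ranges (see [fit_fold()]).
#' @param seed integer seed.
#' @return a list of class `nv_ensemble`: `folds` (list of `fold_model`),
#'   `fold_of` (fold index per training sample), `model_type`,
#'   `feature_names`, `seed`.
#' @export
train_ensemble <- function(x, y, out_dbp, out_sbp,
                           model_type = c("xgb", "lgbm", "rf"), k = 5,
                           nrounds_max = 1000,
                           rf_grid = c(seq(100, 500, by = 100),
                                       seq(600, 1000, by = 50)),
                           seed = 1L) {
  model_type <- match.arg(model_type)
  fold <- assign_folds(out_dbp, out_sbp, k)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    va <- fold == f
    folds[[f]] <- fit_fold(x[!va, , drop = FALSE], y[!va],
                           x[va, , drop = FALSE], y[va],
                           model_type = model_type,
                           nrounds_max = nrounds_max, rf_grid = rf_grid,
                           seed = seed + f, fold_index = f)
  }
  structure(list(folds = folds, fold_of = fold, model_type = model_type,
                 feature_names = colnames(x), seed = seed),
            class = "nv_ensemble")
}

#' Predict with the voting ensemble
#'
#' Each fold model produces a probability, thresholds it with its own
#' validation-tuned threshold, and the final prediction is the majority
#' vote (with an even number of voters a tie resolves positive).
#'
#' @param ensemble an `nv_ensemble`.
#' @param x encoded feature matrix.
#' @return a list of class `nv_prediction`: `prob` (n x k matrix), `votes`
#'   (n x k logical), `final` (logical majority vote).
#' @export
predict_ensemble <- function(ensemble, x) {
  k <- length(ensemble$folds)
  if (k == 0 || any(vapply(ensemble$folds, is.null, TRUE)))
    stop("predict_ensemble: ensemble has missing fold models")
  prob <- vapply(ensemble$folds, fold_model_prob, numeric(nrow(x)), x = x)
  prob <- matrix(prob, nrow = nrow(x), ncol = k)
  votes <- sweep(prob, 2, vapply(ensemble$folds, `[[`, 1, "th"), `>=`)
  structure(list(prob = prob, votes = votes,
                 final = rowSums(votes) >= k / 2 + ifelse(k %% 2 == 1, 0.5, 0)),
            class = "nv_prediction")
}

#' Persist an ensemble's manifest (type, capacities, thresholds) as JSON
#'
#' @param ensemble an `nv_ensemble`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_ensemble_manifest <- function(ensemble, path) {
  man <- list(model_type = ensemble$model_type, seed = ensemble$seed,
              n_features = length(ensemble$feature_names),
              folds = lapply(ensemble$folds, function(f)
                list(fold = f$fold_index, capacity = f$capacity,
                     th = f$th, best_val_loss = f$best_val_loss)))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
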