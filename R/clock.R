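#' Hyperparameter search space for the gradient-boosted age regressor
#'
#' Ranges for the random search driven by [tune_hyperparameters()]: learning
#' rate (log-uniform), tree depth (the tree-complexity control), minimum
#' child weight (minimum leaf size), and row/feature subsampling, plus the
#' tree-count cap used with early stopping. `n_trials = 200` matches the
#' full-scale search; the desk default of 30 trials is appropriate for
#' simulated cohorts of a few thousand subjects.
#'
#' @param n_trials Number of random configurations to evaluate.
#' @param k_folds Cross-validation folds.
#' @param eta,max_depth,min_child_weight,subsample,colsample_bytree Length-2
#'   numeric ranges.
#' @param nrounds_max Maximum boosting rounds (early stopping decides the
#'   effective count).
#' @param early_stopping Early-stopping patience in rounds.
#' @return A `clock_search_space` list.
#' @export
clock_search_space <- function(n_trials = 30, k_folds = 5,
                               eta = c(0.03, 0.3),
                               max_depth = c(2L, 8L),
                               min_child_weight = c(1, 20),
                               subsample = c(0.6, 1),
                               colsample_bytree = c(0.3, 1),
                               nrounds_max = 200, early_stopping = 10) {
  assert_count(n_trials, "n_trials")
  assert_count(k_folds, "k_folds", min = 2)
  structure(
    list(n_trials = as.integer(n_trials), k_folds = as.integer(k_folds),
         eta = eta, max_depth = max_depth,
         min_child_weight = min_child_weight, subsample = subsample,
         colsample_bytree = colsample_bytree,
         nrounds_max = as.integer(nrounds_max),
         early_stopping = as.integer(early_stopping)),
    class = "clock_search_space"
  )
}

#' Split a cohort into training and test sets
#'
#' Seed-deterministic random partition; the training size is
#' `round(train_fraction * n)`, giving a 7:3 split at the default fraction.
#'
#' @param cohort Cohort tibble with a `subject_id` column.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles (disjoint, exhaustive).
#' @export
split_train_test <- function(cohort, train_fraction = 0.7, seed = 1) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1)")
  }
  n <- nrow(cohort)
  if (n < 10) abort("need at least 10 subjects to split")
  n_train <- round(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = cohort[sort(idx), ], test = cohort[sort(setdiff(seq_len(n), idx)), ])
}

# --- internal xgboost plumbing ---------------------------------------------

xgb_params <- function(hp, seed) {
  list(objective = "reg:squarederror", eta = hp$eta,
       max_depth = as.integer(hp$max_depth),
       min_child_weight = hp$min_child_weight,
       subsample = hp$subsample, colsample_bytree = hp$colsample_bytree,
       nthread = 1, seed = as.integer(seed))
}

xgb_fit <- function(x, y, hp, nrounds, seed) {
  xgboost::xgb.train(
    params = xgb_params(hp, seed),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = nrounds, verbose = 0
  )
}

# Mean |SHAP| per feature, computed by exact tree-path attribution.
shap_importance <- function(booster, x) {
  contrib <- predict(booster, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  contrib <- contrib[, setdiff(colnames(contrib), "BIAS"), drop = FALSE]
  colMeans(abs(contrib))
}

fold_assignment <- function(n, k, seed) {
  if (k > n) abort("more folds than subjects")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

# k-fold CV of one configuration with early stopping; returns mean
# out-of-fold R^2 (1 - MSE/Var) and the per-fold best iteration counts.
cv_evaluate <- function(x, y, hp, folds, nrounds_max, early_stopping, seed) {
  k <- max(folds)
  r2 <- numeric(k); iters <- integer(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
    dva <- xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], label = y[!tr])
    m <- xgboost::xgb.train(
      params = xgb_params(hp, seed + f), data = dtr, nrounds = nrounds_max,
      evals = list(val = dva), early_stopping_rounds = early_stopping,
      verbose = 0
    )
    log <- attributes(m)$evaluation_log
    best_rmse <- min(log$val_rmse)
    iters[f] <- as.integer(xgboost::xgb.attr(m, "best_iteration"))
    v <- var(y[!tr]) * (sum(!tr) - 1) / sum(!tr)
    r2[f] <- 1 - best_rmse^2 / v
  }
  list(mean_r2 = mean(r2), fold_r2 = r2, nrounds = max(1L, as.integer(round(mean(iters)))))
}

#' Tune clock hyperparameters by random search
#'
#' Samples `n_trials` configurations from the search space and evaluates each
#' by k-fold cross-validation on the training set with early stopping,
#' maximising the mean out-of-fold R-squared. The winning configuration's
#' boosting-round count is the rounded mean of the per-fold early-stopped
#' best iterations.
#'
#' @param train Training cohort tibble (must contain `age`).
#' @param candidate_proteins Protein columns used as features.
#' @param space A [clock_search_space()].
#' @param seed Integer seed (controls both the sampled configurations and the
#'   CV folds).
#' @return List: `best` (named hyperparameter list including `nrounds`),
#'   `trials` (tibble log with per-trial configuration and mean/per-fold R^2).
#' @export
tune_hyperparameters <- function(train, candidate_proteins,
                                 space = clock_search_space(), seed = 1) {
  if (length(candidate_proteins) == 0) abort("empty candidate protein set")
  x <- protein_matrix(train, candidate_proteins)
  y <- train$age
  folds <- fold_assignment(nrow(x), space$k_folds, seed)
  configs <- with_seed(seed + 1, {
    tibble(
      trial = seq_len(space$n_trials),
      eta = exp(runif(space$n_trials, log(space$eta[1]), log(space$eta[2]))),
      max_depth = {
        depths <- seq(space$max_depth[1], space$max_depth[2])
        depths[sample.int(length(depths), space$n_trials, replace = TRUE)]
      },
      min_child_weight = runif(space$n_trials, space$min_child_weight[1],
                               space$min_child_weight[2]),
      subsample = runif(space$n_trials, space$subsample[1], space$subsample[2]),
      colsample_bytree = runif(space$n_trials, space$colsample_bytree[1],
                               space$colsample_bytree[2])
    )
  })
  res <- purrr::pmap(configs, function(trial, ...) {
    hp <- list(...)
    out <- tryCatch(
      cv_evaluate(x, y, hp, folds, space$nrounds_max, space$early_stopping,
                  seed + trial),
      error = function(e) NULL
    )
    if (is.null(out)) return(tibble(mean_r2 = NA_real_, nrounds = NA_integer_,
                                    fold_r2 = list(NULL)))
    tibble(mean_r2 = out$mean_r2, nrounds = out$nrounds,
           fold_r2 = list(out$fold_r2))
  })
  trials <- bind_cols(configs, bind_rows(res))
  if (all(is.na(trials$mean_r2))) abort("all tuning trials failed to fit")
  best_row <- trials[which.max(trials$mean_r2), ]
  best <- list(eta = best_row$eta, max_depth = best_row$max_depth,
               min_child_weight = best_row$min_child_weight,
               subsample = best_row$subsample,
               colsample_bytree = best_row$colsample_bytree,
               nrounds = best_row$nrounds)
  list(best = best, trials = trials)
}

#' Boruta shadow-feature selection
#'
#' Iterative all-relevant feature selection: at each trial, every surviving
#' real feature gets one shadow copy made by independently permuting its
#' column; a regressor is fitted on real + shadow features; features are
#' scored by mean |SHAP| on the training data; and every real feature whose
#' importance is lower than the maximum over all shadow importances (the
#' "100% threshold") is removed. Stops when a trial removes nothing or after
#' `max_trials`.
#'
#' @param train Training cohort tibble (must contain `age`).
#' @param candidate_proteins Features to select among (>= 2).
#' @param hyperparameters Named list from [tune_hyperparameters()] (`$best`).
#' @param max_trials Maximum Boruta trials; default 200.
#' @param seed Integer seed.
#' @return List: `selected` (character vector of survivors; may be empty,
#'   with a warning), `log` (tibble: trial, n_candidates, n_removed,
#'   max_shadow_importance, removed list-column).
#' @export
boruta_select <- function(train, candidate_proteins, hyperparameters,
                          max_trials = 200, seed = 1) {
  if (length(candidate_proteins) < 2) abort("need >= 2 candidate proteins")
  x_full <- protein_matrix(train, candidate_proteins)
  y <- train$age
  survivors <- candidate_proteins
  log <- list()
  with_seed(stage_seed(seed, "boruta"), {
    for (trial in seq_len(max_trials)) {
      x <- x_full[, survivors, drop = FALSE]
      shadows <- apply(x, 2, sample)
      colnames(shadows) <- paste0(".shadow_", survivors)
      xs <- cbind(x, shadows)
      m <- xgb_fit(xs, y, hyperparameters,
                   nrounds = hyperparameters$nrounds,
                   seed = seed + trial)
      imp <- shap_importance(m, xs)
      shadow_max <- max(imp[colnames(shadows)])
      removed <- survivors[imp[survivors] < shadow_max]
      log[[trial]] <- tibble(
        trial = trial, n_candidates = length(survivors),
        n_removed = length(removed), max_shadow_importance = shadow_max,
        removed = list(removed)
      )
      survivors <- setdiff(survivors, removed)
      if (length(removed) == 0 || length(survivors) == 0) break
    }
  })
  if (length(survivors) == 0) {
    warn("Boruta removed every candidate feature")
  }
  list(selected = survivors, log = bind_rows(log))
}

#' Fit the final age regressor
#'
#' Trains a gradient-boosted tree regressor of decimal age on the selected
#' proteins with the supplied (re-tuned) hyperparameters. Missing protein
#' values are handled natively: at each split, missing values are routed to
#' the loss-minimising side.
#'
#' @param train Training cohort tibble.
#' @param selected_proteins Feature columns (nonempty).
#' @param hyperparameters Named list including `nrounds`.
#' @param seed Integer seed.
#' @return A `clock_fit` object (booster + feature list + metadata).
#' @export
fit_final <- function(train, selected_proteins, hyperparameters, seed = 1) {
  if (length(selected_proteins) == 0) abort("empty selected protein set")
  y <- train$age
  if (sd(y) == 0) abort("constant age target; cannot fit a clock")
  x <- protein_matrix(train, selected_proteins)
  booster <- xgb_fit(x, y, hyperparameters, hyperparameters$nrounds, seed)
  structure(
    list(booster = booster, proteins = selected_proteins,
         hyperparameters = hyperparameters, seed = seed,
         importance = shap_importance(booster, x)),
    class = "clock_fit"
  )
}

#' @export
predict.clock_fit <- function(object, newdata, ...) {
  x <- protein_matrix(newdata, object$proteins)
  as.numeric(predict(object$booster, xgboost::xgb.DMatrix(x)))
}

#' Out-of-fold proteomic age for every subject
#'
#' Partitions the cohort into `k` folds; each subject's proteomic age comes
#' from the one model whose training data excluded them, so every subject is
#' predicted exactly once without leakage.
#'
#' @param cohort Preprocessed cohort tibble.
#' @param selected_proteins Feature columns.
#' @param hyperparameters Named list including `nrounds`.
#' @param k Folds; default 5.
#' @param seed Integer seed.
#' @return List: `predictions` (tibble: subject_id, age, proteomic_age,
#'   fold), `models` (list of `clock_fit`, one per fold), `folds`
#'   (assignment vector).
#' @export
predict_oof <- function(cohort, selected_proteins, hyperparameters, k = 5,
                        seed = 1) {
  n <- nrow(cohort)
  folds <- fold_assignment(n, k, stage_seed(seed, "oof"))
  pred <- rep(NA_real_, n)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    fit <- fit_final(cohort[folds != f, ], selected_proteins, hyperparameters,
                     seed = seed + f)
    pred[folds == f] <- predict(fit, cohort[folds == f, ])
    models[[f]] <- fit
  }
  list(
    predictions = tibble(subject_id = cohort$subject_id, age = cohort$age,
                         proteomic_age = pred, fold = folds),
    models = models, folds = folds
  )
}

#' Train one organ (or organismal) aging clock end to end
#'
#' The full training pipeline: 7:3 train/test split; hyperparameter search;
#' Boruta shadow-feature selection; a second hyperparameter search on the
#' selected subset; final fit evaluated on the held-out test set; and
#' out-of-fold proteomic age for the whole cohort via k-fold
#' cross-validation with the final hyperparameters.
#'
#' @param cohort Preprocessed cohort tibble (`subject_id`, `age`, protein
#'   columns).
#' @param candidate_proteins Candidate features (all proteins for the
#'   organismal clock, one organ's enriched proteins for an organ clock).
#' @param organ Label stored on the model.
#' @param space A [clock_search_space()].
#' @param train_fraction Training fraction for the outer split.
#' @param boruta_max_trials Boruta trial cap.
#' @param seed Master seed; stage seeds are derived from it.
#' @return An `organ_clock` object.
#' @export
train_clock <- function(cohort, candidate_proteins, organ = "organismal",
                        space = clock_search_space(), train_fraction = 0.7,
                        boruta_max_trials = 200, seed = 1) {
  split <- split_train_test(cohort, train_fraction, stage_seed(seed, "split"))
  tune1 <- tune_hyperparameters(split$train, candidate_proteins, space,
                                stage_seed(seed, "tune"))
  bor <- boruta_select(split$train, candidate_proteins, tune1$best,
                       max_trials = boruta_max_trials, seed = seed)
  selected <- bor$selected
  if (length(selected) == 0) {
    warn("Boruta selected no proteins; falling back to the candidate set")
    selected <- candidate_proteins
  }
  tune2 <- tune_hyperparameters(split$train, selected, space,
                                stage_seed(seed, "retune"))
  fit <- fit_final(split$train, selected, tune2$best,
                   seed = stage_seed(seed, "fit"))
  test_pred <- predict(fit, split$test)
  evaluation <- tibble(
    r = stats::cor(split$test$age, test_pred),
    r2 = r_squared(split$test$age, test_pred),
    n_test = nrow(split$test),
    cv_r2 = tune2$best_cv_r2 %||% max(tune2$trials$mean_r2, na.rm = TRUE)
  )
  oof <- predict_oof(cohort, selected, tune2$best, k = space$k_folds,
                     seed = seed)
  structure(
    list(organ = organ, candidate_proteins = candidate_proteins,
         selected_proteins = selected,
         hyperparameters = list(initial = tune1$best, final = tune2$best),
         final_fit = fit, fold_models = oof$models,
         fold_assignment = oof$folds, oof = oof$predictions,
         evaluation = evaluation,
         tune_log = list(initial = tune1$trials, final = tune2$trials),
         boruta_log = bor$log,
         train_ids = split$train$subject_id, test_ids = split$test$subject_id,
         seed = seed),
    class = "organ_clock"
  )
}

#' @export
print.organ_clock <- function(x, ...) {
  cat(sprintf("Proteomic aging clock [%s]\n", x$organ))
  cat(sprintf("  candidates: %d  selected: %d\n",
              length(x$candidate_proteins), length(x$selected_proteins)))
  cat(sprintf("  held-out r = %.3f, r2 = %.3f (n = %d)\n",
              x$evaluation$r, x$evaluation$r2, x$evaluation$n_test))
  invisible(x)
}

#' Project a trained clock onto an external cohort
#'
#' Predicts proteomic age as the mean of the clock's fold-model predictions.
#' The external cohort must contain every selected protein (after being
#' preprocessed under the chosen scaling mode); missing columns raise an
#' error naming them.
#'
#' @param clock An `organ_clock`.
#' @param external_cohort Preprocessed external cohort tibble.
#' @return Tibble: subject_id, proteomic_age.
#' @export
project_clock <- function(clock, external_cohort) {
  missing <- setdiff(clock$selected_proteins, names(external_cohort))
  if (length(missing) > 0) {
    abort(paste0("external cohort lacks required protein column(s): ",
                 paste(missing, collapse = ", ")))
  }
  preds <- vapply(clock$fold_models, predict, numeric(nrow(external_cohort)),
                  newdata = external_cohort)
  preds <- matrix(preds, nrow = nrow(external_cohort))
  tibble(subject_id = external_cohort$subject_id,
         proteomic_age = rowMeans(preds))
}
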