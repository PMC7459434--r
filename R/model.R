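# Stratified splitting, cross-validated tuning, gradient-boosted fitting,
# month-level prediction and frequency-based feature importance.
#
# All splitting and fold assignment happens at the patient level: every
# month of a patient stays on one side of the split and in one fold, so no
# within-patient information crosses the train/validation boundary.

#' Split the cohort into training and test patients
#'
#' Event and event-free patients are each split `fraction` : `1 - fraction`
#' and recombined, so the test set preserves the cohort's event prevalence.
#' Training patients are further assigned to `n_folds` cross-validation
#' folds, again stratified by event status.
#'
#' @param registry Registry tibble with the `sbce` indicator.
#' @param fraction Training fraction per stratum (default 0.8); the training
#'   stratum size is `round(fraction * n)`.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `cohort_split`: list with `train_ids`, `test_ids`, `folds`
#'   (tibble `patient_id`, `fold`), `fraction`, `n_folds`, `seed`.
#' @export
split_cohort <- function(registry, fraction = 0.8, n_folds = 5, seed) {
  strata <- split(sort(as.character(registry$patient_id)), registry$sbce[
    order(as.character(registry$patient_id))])
  small <- vapply(strata, length, 1L) < n_folds
  if (any(small)) {
    abort(sprintf("stratum with fewer than %d patients cannot form %d folds",
                  n_folds, n_folds), class = "recurmine_config_error")
  }
  with_seed(seed, {
    plan <- lapply(strata, function(ids) {
      ids <- sample(ids)
      n_train <- round(fraction * length(ids))
      train <- ids[seq_len(n_train)]
      list(train = train,
           test = ids[-seq_len(n_train)],
           folds = tibble(patient_id = train,
                          fold = rep_len(seq_len(n_folds), length(train))))
    })
  })
  structure(
    list(train_ids = unlist(lapply(plan, `[[`, "train"), use.names = FALSE),
         test_ids = unlist(lapply(plan, `[[`, "test"), use.names = FALSE),
         folds = bind_rows(lapply(plan, `[[`, "folds")),
         fraction = fraction, n_folds = n_folds, seed = seed),
    class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d train / %d test patients, %d folds (seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$n_folds, x$seed))
  invisible(x)
}

#' Default hyperparameter grid
#'
#' Tree depth 3 or 6 crossed with learning rate 0.1 or 0.3; the number of
#' boosting rounds is chosen by early stopping on out-of-fold AUC rather
#' than being part of the grid.
#'
#' @return A data frame with columns `max_depth`, `eta`.
#' @export
default_tune_grid <- function() {
  expand.grid(max_depth = c(3L, 6L), eta = c(0.1, 0.3))
}

xgb_data <- function(features, ids = NULL) {
  fm <- feature_matrix_of(features)
  lab <- features$label
  if (!is.null(ids)) {
    keep <- features$patient_id %in% ids
    fm <- fm[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  xgboost::xgb.DMatrix(fm, label = lab, nthread = 1)
}

base_params <- function(params) {
  c(list(objective = "binary:logistic", eval_metric = "auc", nthread = 1),
    params)
}

#' Tune hyperparameters by patient-level cross-validation
#'
#' For every grid setting, fits on four of the five patient folds and
#' evaluates month-level AUC on the held-out fold, with early stopping; the
#' setting with the best mean out-of-fold AUC wins, and the final round
#' count is the mean best iteration across its folds.
#'
#' @param features An `sbce_features` matrix (training patients are taken
#'   from `split`).
#' @param split A `cohort_split`.
#' @param grid Data frame of candidate settings (columns are xgboost
#'   parameters); default [default_tune_grid()].
#' @param nrounds_max,early_stopping Boosting-round budget and early-stopping
#'   patience for each fold fit.
#' @param seed Integer seed for the fold fits.
#' @return List with `params` (best setting as a list), `nrounds`, and `cv`
#'   (tibble of per-setting mean out-of-fold AUC).
#' @export
tune_sbce_model <- function(features, split, grid = default_tune_grid(),
                            nrounds_max = 300, early_stopping = 20, seed = 1) {
  if (is.null(grid) || nrow(grid) == 0) {
    abort("empty hyperparameter grid", class = "recurmine_config_error")
  }
  folds <- split$folds
  results <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    fold_stats <- purrr::map_dfr(sort(unique(folds$fold)), function(f) {
      tr_ids <- folds$patient_id[folds$fold != f]
      va_ids <- folds$patient_id[folds$fold == f]
      dtr <- xgb_data(features, tr_ids)
      dva <- xgb_data(features, va_ids)
      fit <- with_seed(seed + f, xgboost::xgb.train(
        params = base_params(params), data = dtr, nrounds = nrounds_max,
        evals = list(val = dva), verbose = 0,
        early_stopping_rounds = early_stopping, maximize = TRUE))
      tibble(fold = f,
             auc = as.numeric(xgboost::xgb.attr(fit, "best_score")),
             best_iter = as.integer(xgboost::xgb.attr(fit, "best_iteration")))
    })
    tibble(setting = i, !!!params,
           mean_auc = mean(fold_stats$auc),
           nrounds = max(1L, as.integer(round(mean(fold_stats$best_iter)))))
  })
  best <- results[which.max(results$mean_auc), ]
  param_names <- names(grid)
  list(params = as.list(best[param_names]),
       nrounds = best$nrounds,
       cv = results)
}

#' Fit the gradient-boosted person-month classifier
#'
#' @param features An `sbce_features` matrix to train on (already restricted
#'   to training patients).
#' @param params List of xgboost parameters (for example
#'   `list(max_depth = 3, eta = 0.3)`).
#' @param nrounds Number of boosting rounds.
#' @param seed Integer seed; refitting with the same seed, data and
#'   parameters reproduces identical predictions.
#' @param scale_pos_weight Optional class-imbalance weight passed to the
#'   ensemble (`NULL`, the default, leaves weighting off).
#' @return An `sbce_model`: list with the fitted `booster`, `params`,
#'   `nrounds`, `feature_names` and `seed`.
#' @export
fit_sbce_model <- function(features, params = list(max_depth = 3L, eta = 0.3),
                           nrounds = 100, seed = 1, scale_pos_weight = NULL) {
  if (nrow(features) == 0) {
    abort("empty feature matrix", class = "recurmine_config_error")
  }
  if (length(unique(features$label)) < 2) {
    abort("training labels contain a single class",
          class = "recurmine_config_error")
  }
  if (!is.null(scale_pos_weight)) params$scale_pos_weight <- scale_pos_weight
  dtr <- xgb_data(features)
  booster <- with_seed(seed, xgboost::xgb.train(
    params = base_params(params), data = dtr, nrounds = nrounds, verbose = 0))
  structure(
    list(booster = booster, params = params, nrounds = nrounds,
         feature_names = attr(features, "feature_names"), seed = seed),
    class = "sbce_model")
}

#' @export
print.sbce_model <- function(x, ...) {
  cat(sprintf("<sbce_model> gradient-boosted trees: %d rounds, %d features (seed %d)\n",
              x$nrounds, length(x$feature_names), x$seed))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Predict month-level post-event probabilities
#'
#' @param model An `sbce_model`.
#' @param features An `sbce_features` matrix with the same feature names the
#'   model was trained on.
#' @return A tibble `patient_id`, `month_index`, `label` (carried through
#'   for evaluation), `probability`.
#' @export
predict_months <- function(model, features) {
  fn <- attr(features, "feature_names")
  if (!identical(fn, model$feature_names)) {
    abort("feature names do not match the fitted model",
          class = "recurmine_schema_error")
  }
  if (nrow(features) == 0) {
    return(tibble(patient_id = character(), month_index = integer(),
                  label = integer(), probability = numeric()))
  }
  p <- predict(model$booster,
               xgboost::xgb.DMatrix(feature_matrix_of(features), nthread = 1))
  tibble(patient_id = features$patient_id,
         month_index = features$month_index,
         label = features$label,
         probability = as.numeric(p))
}

#' Rank features by frequency of use across the ensemble's trees
#'
#' Importance is the share of splits using each feature across all trees
#' (the features most commonly present in the submodels); features never
#' used get importance 0. Ties are broken by the stored feature order.
#'
#' @param model An `sbce_model`.
#' @param top_k Number of features to return (default 20; larger than the
#'   feature count returns all).
#' @return Tibble `rank`, `feature`, `importance`, nonincreasing in
#'   importance.
#' @export
feature_importance <- function(model, top_k = 20) {
  imp <- as.data.frame(xgboost::xgb.importance(model = model$booster))
  all <- tibble(feature = model$feature_names) %>%
    left_join(tibble(feature = imp$Feature, importance = imp$Frequency),
              by = "feature") %>%
    mutate(importance = tidyr::replace_na(.data$importance, 0),
           .order = row_number()) %>%
    arrange(dplyr::desc(.data$importance), .data$.order) %>%
    mutate(rank = row_number()) %>%
    select("rank", "feature", "importance")
  head(all, top_k)
}

#' @method tidy sbce_model
#' @export
tidy.sbce_model <- function(x, ...) {
  feature_importance(x, top_k = length(x$feature_names))
}

#' @method glance sbce_model
#' @export
glance.sbce_model <- function(x, ...) {
  tibble(nrounds = x$nrounds,
         max_depth = x$params$max_depth %||% NA_integer_,
         eta = x$params$eta %||% NA_real_,
         n_features = length(x$feature_names),
         seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
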