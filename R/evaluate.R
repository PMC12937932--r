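#' Binary classification metrics
#'
#' AUC is the rank (Mann-Whitney) statistic with midrank credit of 0.5 for
#' tied scores. Accuracy, sensitivity (true positive rate) and specificity
#' (true negative rate) use class predictions at `prob_threshold`.
#'
#' @param y_true Binary labels (1/`"case"` = positive class).
#' @param scores Predicted probabilities or scores (higher = more positive).
#' @param prob_threshold Operating point for the threshold metrics
#'   (default 0.5).
#' @return Named numeric vector `auc`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
binary_metrics <- function(y_true, scores, prob_threshold = 0.5) {
  y <- as_binary(y_true)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present in y_true", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= prob_threshold)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  c(auc = auc,
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / n1,
    specificity = tn / n0)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin, so every fold's class proportions are within one
# subject of the global proportions. Uses the current RNG stream.
stratified_folds <- function(y, k) {
  y <- as_binary(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop("class with fewer members (", length(idx),
           ") than folds (", k, ")", call. = FALSE)
    }
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Default nested cross-validation configuration
#'
#' @param outer_folds,outer_repeats Outer loop: stratified k-fold, repeated
#'   (defaults 10 x 3).
#' @param inner_folds Inner stratified folds for hyperparameter scoring
#'   (default 4).
#' @param search_iterations Randomized-search draws per outer fold
#'   (default 20).
#' @param vfs_k_range Integer range for the number of selected features
#'   (default 25..100).
#' @param vfs_lr_c_range Log-uniform range for the L1-logistic inverse
#'   regularization strength (default 1e-3..1e3).
#' @param seed Global seed; per-fold seeds are derived from it together
#'   with the repeat and fold indices.
#' @return A `CVConfig` (named list). The classifier search space (number
#'   of trees 100..500, depth 2..6, learning rate log-uniform 0.01..0.3,
#'   subsample and column subsample 0.6..1, L1/L2 regularization
#'   log-uniform 1e-3..10) is fixed in the configuration and logged with
#'   every run.
#' @export
cv_config <- function(outer_folds = 10L, outer_repeats = 3L,
                      inner_folds = 4L, search_iterations = 20L,
                      vfs_k_range = c(25L, 100L),
                      vfs_lr_c_range = c(1e-3, 1e3), seed = 1L) {
  if (outer_folds < 2L || inner_folds < 2L || search_iterations < 1L) {
    stop("invalid cross-validation configuration", call. = FALSE)
  }
  structure(list(
    outer_folds = as.integer(outer_folds),
    outer_repeats = as.integer(outer_repeats),
    inner_folds = as.integer(inner_folds),
    search_iterations = as.integer(search_iterations),
    vfs_k_range = vfs_k_range, vfs_lr_c_range = vfs_lr_c_range,
    n_estimators_range = c(100L, 500L), depth_range = c(2L, 6L),
    eta_range = c(0.01, 0.3), subsample_range = c(0.6, 1.0),
    colsample_range = c(0.6, 1.0), reg_range = c(1e-3, 10),
    refit_metric = "auc", seed = as.integer(seed)
  ), class = "CVConfig")
}

log_unif <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))

sample_search_configs <- function(config, n_features) {
  n <- config$search_iterations
  k_hi <- min(config$vfs_k_range[2L], n_features)
  k_lo <- min(config$vfs_k_range[1L], k_hi)
  lapply(seq_len(n), function(i) list(
    vfs_k = sample(seq.int(k_lo, k_hi), 1L),
    vfs_lr_c = log_unif(1L, config$vfs_lr_c_range[1L],
                        config$vfs_lr_c_range[2L]),
    nrounds = sample(seq.int(config$n_estimators_range[1L],
                             config$n_estimators_range[2L], by = 50L), 1L),
    max_depth = sample(seq.int(config$depth_range[1L],
                               config$depth_range[2L]), 1L),
    eta = log_unif(1L, config$eta_range[1L], config$eta_range[2L]),
    subsample = runif(1L, config$subsample_range[1L],
                      config$subsample_range[2L]),
    colsample_bytree = runif(1L, config$colsample_range[1L],
                             config$colsample_range[2L]),
    alpha = log_unif(1L, config$reg_range[1L], config$reg_range[2L]),
    lambda = log_unif(1L, config$reg_range[1L], config$reg_range[2L])
  ))
}

fold_seed <- function(seed, rep, fold) {
  as.integer((abs(seed) %% 1000003L) * 1009L + rep * 101L + fold) %% 2147483647L
}

# Fit the full pipeline (cleaning -> voting feature selection -> gradient
# boosted trees) on training rows only.
fit_pipeline <- function(V_train, y_train, params, seed = 0L) {
  stats <- fit_clean_stats(V_train, seq_len(nrow(V_train)))
  Xc <- apply_clean_stats(V_train, stats)
  sel <- vote_select(Xc, y_train, vfs_k = params$vfs_k,
                     vfs_lr_c = params$vfs_lr_c, seed = seed)
  Xs <- Xc[, sel$selected, drop = FALSE]
  dtrain <- xgboost::xgb.DMatrix(Xs, label = as_binary(y_train))
  xgb_params <- list(
    objective = "binary:logistic", max_depth = params$max_depth,
    eta = params$eta, subsample = params$subsample,
    colsample_bytree = params$colsample_bytree, alpha = params$alpha,
    lambda = params$lambda, nthread = 1, seed = seed
  )
  model <- xgboost::xgb.train(params = xgb_params, data = dtrain,
                              nrounds = params$nrounds, verbose = 0)
  structure(list(clean_stats = stats, selected = sel$selected,
                 vfs_audit = sel$audit, params = params, model = model,
                 feature_names = colnames(V_train)),
            class = "kin_pipeline")
}

predict_pipeline <- function(pipeline, V_new) {
  Xc <- apply_clean_stats(V_new, pipeline$clean_stats)
  Xs <- Xc[, pipeline$selected, drop = FALSE]
  predict(pipeline$model, xgboost::xgb.DMatrix(Xs))
}

#' Nested cross-validation of the similarity-network classifier
#'
#' Outer stratified k-fold cross-validation (repeated) estimates
#' generalization; within each outer training split a randomized search
#' scores candidate configurations (feature-selection size `vfs_k`,
#' L1-logistic strength `vfs_lr_c`, and the gradient-boosted-tree
#' hyperparameters) by inner stratified cross-validation with multi-metric
#' scoring, the configuration with the highest inner mean AUC is refit on
#' the full outer training split, and that refit pipeline is evaluated once
#' on the untouched outer test split. Cleaning statistics and feature
#' selection are fit inside the training side of every split. Per-fold
#' Shapley attributions of the refit pipeline on the held-out subjects are
#' stored for the explainability stage.
#'
#' @param table A `FeatureTable` (typically residualized, not yet cleaned)
#'   or a plain numeric matrix.
#' @param labels Binary group labels, one per subject (`"case"` /
#'   `"control"` or 0/1).
#' @param config A [cv_config()].
#' @param keep_models Store the refit pipeline of every fold (default TRUE;
#'   needed for [fold_attributions()] on new data).
#' @return List with `folds` (list of `FoldResult`: fold id, best
#'   hyperparameters, selected features, test metrics, per-feature mean
#'   |SHAP| and case-signed mean SHAP) and `summary` (mean and SD of each
#'   metric across folds), plus the `config` used.
#' @export
nested_cv <- function(table, labels, config = cv_config(),
                      keep_models = TRUE) {
  V <- if (inherits(table, "FeatureTable")) table$values else as.matrix(table)
  y <- as_binary(labels)
  if (length(y) != nrow(V)) stop("labels do not match rows", call. = FALSE)
  folds_out <- list()
  for (r in seq_len(config$outer_repeats)) {
    rep_seed <- fold_seed(config$seed, r, 0L)
    assign_folds <- with_seed(rep_seed,
                              stratified_folds(y, config$outer_folds))
    for (f in seq_len(config$outer_folds)) {
      test_idx <- which(assign_folds == f)
      train_idx <- setdiff(seq_along(y), test_idx)
      fs <- fold_seed(config$seed, r, f)
      res <- with_seed(fs, run_outer_fold(
        V, y, train_idx, test_idx, config, fs))
      res$repeat_id <- r
      res$fold_id <- f
      if (!keep_models) res$pipeline <- NULL
      folds_out[[length(folds_out) + 1L]] <- res
    }
  }
  metrics <- do.call(rbind, lapply(folds_out, function(x) x$metrics))
  summary <- data.frame(
    metric = colnames(metrics),
    mean = colMeans(metrics),
    sd = apply(metrics, 2L, sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(folds = folds_out, summary = summary, config = config)
}

run_outer_fold <- function(V, y, train_idx, test_idx, config, seed) {
  V_tr <- V[train_idx, , drop = FALSE]
  y_tr <- y[train_idx]
  configs <- sample_search_configs(config, ncol(V))
  inner_assign <- stratified_folds(y_tr, config$inner_folds)
  inner_scores <- matrix(NA_real_, length(configs), 4L,
                         dimnames = list(NULL, c("auc", "accuracy",
                                                 "sensitivity",
                                                 "specificity")))
  for (ci in seq_along(configs)) {
    ms <- matrix(NA_real_, config$inner_folds, 4L)
    for (fi in seq_len(config$inner_folds)) {
      val <- which(inner_assign == fi)
      tr <- setdiff(seq_along(y_tr), val)
      pl <- fit_pipeline(V_tr[tr, , drop = FALSE], y_tr[tr],
                         configs[[ci]], seed = seed)
      scores <- predict_pipeline(pl, V_tr[val, , drop = FALSE])
      ms[fi, ] <- binary_metrics(y_tr[val], scores)
    }
    inner_scores[ci, ] <- colMeans(ms)
  }
  best <- which.max(inner_scores[, "auc"])
  pipeline <- fit_pipeline(V_tr, y_tr, configs[[best]], seed = seed)
  scores <- predict_pipeline(pipeline, V[test_idx, , drop = FALSE])
  metrics <- binary_metrics(y[test_idx], scores)
  attr <- fold_attributions(pipeline, V[test_idx, , drop = FALSE],
                            y[test_idx])
  list(
    best_params = configs[[best]],
    inner_scores = inner_scores,
    selected = pipeline$selected,
    metrics = metrics,
    shap_mean_abs = attr$mean_abs,
    shap_signed_case = attr$signed_case,
    test_idx = test_idx,
    pipeline = pipeline
  )
}
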