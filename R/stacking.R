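# Ensemble stacking classifier for endotype replication. Heterogeneous base
# learners (gradient-boosted trees, random forest, multinomial logistic) are
# fitted per stratified fold; a multinomial logistic meta-learner is trained
# on the stacked out-of-fold class probabilities only, so the meta-learner
# never sees resubstitution predictions.

stack_feature_matrix <- function(table, features = NULL) {
  X <- as.data.frame(table)
  if (!is.null(features)) {
    missing_vars <- setdiff(features, names(X))
    if (length(missing_vars) > 0) {
      abort_endo(paste0("Schema mismatch; missing variable(s): ",
                        paste(missing_vars, collapse = ", ")))
    }
    X <- X[, features, drop = FALSE]
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt to folds cyclically.
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

fit_base_learners <- function(X, y, seed) {
  K <- nlevels(y)
  rf <- ranger::ranger(x = X, y = y, probability = TRUE, num.trees = 300,
                       seed = seed, num.threads = 1)
  gbt <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = K,
                  eta = 0.1, max_depth = 4, subsample = 0.8,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L),
    nrounds = 120, verbose = 0)
  df <- data.frame(.y = y, X, check.names = FALSE)
  mlr <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 200,
                        decay = 1e-3, MaxNWts = 10000)
  list(rf = rf, gbt = gbt, mlr = mlr)
}

predict_base <- function(base, X, K) {
  p_rf <- stats::predict(base$rf, data = X, num.threads = 1)$predictions
  p_gbt <- stats::predict(base$gbt, newdata = xgboost::xgb.DMatrix(X))
  if (is.null(dim(p_gbt))) p_gbt <- matrix(p_gbt, ncol = K, byrow = TRUE)
  p_mlr <- stats::predict(base$mlr, newdata = as.data.frame(X),
                          type = "probs")
  if (is.null(dim(p_mlr))) p_mlr <- matrix(p_mlr, nrow = 1)
  cbind(p_rf, p_gbt, p_mlr)
}

#' Fit an ensemble stacking classifier for endotypes
#'
#' Base learners (random forest, gradient-boosted trees, multinomial
#' logistic regression) are fitted on each training fold of a stratified
#' `folds`-fold scheme; their class probabilities on the held-out fold form
#' the out-of-fold design on which a multinomial logistic meta-learner is
#' trained. Base learners are then refitted on the full data for
#' prediction. Reproducible for a fixed seed.
#'
#' @param table Data frame / matrix of (standardized) numeric features.
#' @param labels Endotype labels (vector or an `endotype_assignment`).
#' @param folds Number of stratified folds.
#' @param seed Integer seed.
#' @return An `endotype_stack` object with out-of-fold accuracy, per-class
#'   recall, and the fitted learners.
#' @export
fit_stacking <- function(table, labels, folds = 5, seed = 1) {
  if (inherits(labels, "endotype_assignment")) labels <- labels$endotype
  X <- stack_feature_matrix(table)
  if (anyNA(X)) abort_endo("Missing values in features; no silent imputation.")
  y <- factor(labels)
  if (nrow(X) != length(y)) abort_endo("`labels` must align with `table` rows.")
  small <- names(which(table(y) < folds))
  if (length(small) > 0) {
    abort_endo(paste0("Class(es) with fewer members than folds: ",
                      paste(small, collapse = ", ")))
  }
  K <- nlevels(y)

  with_seed(sub_seed(seed, "stack"), {
    fold_id <- stratified_folds(y, folds)
    oof <- matrix(NA_real_, nrow = nrow(X), ncol = 3L * K)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      base_f <- fit_base_learners(X[tr, , drop = FALSE], droplevels(y[tr]),
                                  seed = seed + f)
      oof[!tr, ] <- predict_base(base_f, X[!tr, , drop = FALSE], K)
    }
    colnames(oof) <- paste0("p", seq_len(ncol(oof)))
    meta_df <- data.frame(.y = y, oof, check.names = FALSE)
    meta <- nnet::multinom(.y ~ ., data = meta_df, trace = FALSE,
                           maxit = 300, decay = 1e-4, MaxNWts = 10000)
    oof_prob <- stats::predict(meta, newdata = data.frame(oof), type = "probs")
    if (is.null(dim(oof_prob))) oof_prob <- matrix(oof_prob, nrow = 1)
    oof_pred <- levels(y)[max.col(oof_prob)]
    recall <- vapply(levels(y), function(cl) {
      mean(oof_pred[y == cl] == cl)
    }, numeric(1))
    base_full <- fit_base_learners(X, y, seed = seed)

    structure(list(
      base = base_full,
      meta = meta,
      features = colnames(X),
      classes = levels(y),
      folds = folds,
      seed = as.integer(seed),
      oof_probabilities = oof,
      oof_accuracy = mean(oof_pred == as.character(y)),
      class_recall = recall
    ), class = "endotype_stack")
  })
}

#' @export
print.endotype_stack <- function(x, ...) {
  cat(sprintf("<endotype_stack> %d classes, %d features, %d-fold OOF accuracy %.3f\n",
              length(x$classes), length(x$features), x$folds, x$oof_accuracy))
  invisible(x)
}

#' Per-class out-of-fold recall of a stacking model
#' @param x An `endotype_stack`.
#' @param ... Unused.
#' @return Tibble with `endotype` and `oof_recall`.
#' @method tidy endotype_stack
#' @export
tidy.endotype_stack <- function(x, ...) {
  tibble::tibble(endotype = x$classes, oof_recall = unname(x$class_recall))
}

#' One-row summary of a stacking model
#' @param x An `endotype_stack`.
#' @param ... Unused.
#' @return Tibble with out-of-fold accuracy and macro recall.
#' @method glance endotype_stack
#' @export
glance.endotype_stack <- function(x, ...) {
  tibble::tibble(oof_accuracy = x$oof_accuracy,
                 macro_recall = mean(x$class_recall),
                 n_classes = length(x$classes),
                 folds = x$folds)
}

#' Predict endotypes with a fitted stacking model
#'
#' New cohorts must be standardized with the training cohort's statistics
#' (see [zstd_apply()]) and contain the training feature schema. Missing
#' values are an error - there is no silent imputation.
#'
#' @param model An `endotype_stack`.
#' @param table Data frame / matrix of features.
#' @return Tibble with `endotype` (argmax class) and one probability column
#'   per class (`p1`..`pK`, rows summing to 1).
#' @export
predict_endotypes <- function(model, table) {
  stopifnot(inherits(model, "endotype_stack"))
  X <- stack_feature_matrix(table, model$features)
  if (anyNA(X)) abort_endo("Missing values in features; no silent imputation.")
  K <- length(model$classes)
  base_prob <- predict_base(model$base, X, K)
  colnames(base_prob) <- paste0("p", seq_len(ncol(base_prob)))
  prob <- stats::predict(model$meta, newdata = data.frame(base_prob),
                         type = "probs")
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1)
  prob <- prob / rowSums(prob)
  colnames(prob) <- paste0("p", seq_len(K))
  out <- tibble::tibble(endotype = as.integer(model$classes[max.col(prob)]))
  dplyr::bind_cols(out, tibble::as_tibble(prob))
}

#' @export
predict.endotype_stack <- function(object, newdata, ...) {
  predict_endotypes(object, newdata)
}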