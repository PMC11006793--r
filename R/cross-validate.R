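#' Stratified k-fold cross-validation of an end-to-end model
#'
#' Folds are stratified by label: within each class, indices are shuffled
#' under `seed` and assigned to folds by position modulo `k`, so fold sizes
#' differ by at most one. Feature tables are re-fitted on each fold's
#' training part only, so no held-out record ever contributes to the
#' probability tables it is scored against.
#'
#' @param pos_train,neg_train `orf_dataset`s.
#' @param method,hyperparameters,seed see [train_classifier()].
#' @param schema a [feature_schema].
#' @param k number of folds (default 10).
#' @param cutoff decision threshold for the per-fold confusion counts.
#' @param pseudocount table smoothing.
#' @return list with `mean` (metric list averaged over folds, including
#'   `roc_auc` and `pr_auc`), `folds` (per-fold metric rows) and `k`.
#' @export
cross_validate <- function(pos_train, neg_train, method = "RF",
                           hyperparameters = list(),
                           schema = feature_schema("reduced33"),
                           k = 10L, seed = 42L, cutoff = 0.5,
                           pseudocount = 1) {
  if (nrow(pos_train) < k || nrow(neg_train) < k) {
    stop("each class needs at least k records for ", k, "-fold CV")
  }
  set.seed(as.integer(seed))
  fold_pos <- fold_assignment(nrow(pos_train), k)
  fold_neg <- fold_assignment(nrow(neg_train), k)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    p_tr <- pos_train[fold_pos != f, , drop = FALSE]
    n_tr <- neg_train[fold_neg != f, , drop = FALSE]
    p_te <- pos_train[fold_pos == f, , drop = FALSE]
    n_te <- neg_train[fold_neg == f, , drop = FALSE]
    tables <- fit_feature_tables(p_tr, n_tr, pseudocount)
    X_tr <- rbind(encode_dataset(p_tr, tables, schema),
                  encode_dataset(n_tr, tables, schema))
    y_tr <- c(rep(TRUE, nrow(p_tr)), rep(FALSE, nrow(n_tr)))
    X_te <- rbind(encode_dataset(p_te, tables, schema),
                  encode_dataset(n_te, tables, schema))
    y_te <- c(rep(TRUE, nrow(p_te)), rep(FALSE, nrow(n_te)))
    model <- train_classifier(X_tr, y_tr, method, hyperparameters,
                              seed = seed + f)
    scores <- score_matrix(model, X_te)
    fold_rows[[f]] <- fold_metrics(scores, y_te, cutoff)
  }
  summarize_folds(fold_rows, k)
}

# shuffled index modulo k: balanced fold sizes within each class
fold_assignment <- function(n, k) {
  (sample.int(n) - 1L) %% k + 1L
}

fold_metrics <- function(scores, y, cutoff) {
  m <- compute_metrics(confusion(scores, y, cutoff))
  m$roc_auc <- curve_and_auc(scores, y, "roc")$auc
  m$pr_auc <- curve_and_auc(scores, y, "pr")$auc
  m
}

summarize_folds <- function(fold_rows, k) {
  metric_names <- c("SN", "SP", "PRE", "ACC", "F1S", "HM", "MCC",
                    "roc_auc", "pr_auc")
  means <- lapply(metric_names, function(nm) {
    mean(vapply(fold_rows, function(r) r[[nm]], numeric(1L)))
  })
  names(means) <- metric_names
  list(mean = means, folds = fold_rows, k = k)
}

#' Cross-validate a classifier on a fixed feature matrix
#'
#' Matrix-level counterpart of [cross_validate()] for cases where the
#' features are already computed (e.g. incremental feature selection over a
#' ranked list, or synthetic feature matrices). Stratified folds as in
#' [cross_validate()]; no table refitting is involved because the features
#' carry no fitted state.
#'
#' @param X feature matrix.
#' @param y labels.
#' @inheritParams cross_validate
#' @return as [cross_validate()].
#' @export
cross_validate_matrix <- function(X, y, method = "RF",
                                  hyperparameters = list(),
                                  k = 10L, seed = 42L, cutoff = 0.5) {
  truth <- as_logical_labels(y)
  if (sum(truth) < k || sum(!truth) < k) {
    stop("each class needs at least k samples for ", k, "-fold CV")
  }
  X <- as.matrix(X)
  set.seed(as.integer(seed))
  fold <- integer(length(truth))
  fold[truth] <- fold_assignment(sum(truth), k)
  fold[!truth] <- fold_assignment(sum(!truth), k)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    model <- train_classifier(X[fold != f, , drop = FALSE], truth[fold != f],
                              method, hyperparameters, seed = seed + f)
    scores <- score_matrix(model, X[fold == f, , drop = FALSE])
    fold_rows[[f]] <- fold_metrics(scores, truth[fold == f], cutoff)
  }
  summarize_folds(fold_rows, k)
}
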