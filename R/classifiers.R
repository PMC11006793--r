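#' @title Coding-potential classifiers
#' @description
#' Four classifier families are supported behind one interface: logistic
#' regression (`"LR"`), support vector machine (`"SVM"`, RBF kernel by
#' default), random forest (`"RF"`, the default — with `mtry` at the square
#' root of the feature count it is the best-performing family for this task)
#' and gradient tree boosting (`"GTB"`). All emit a positive-class score in
#' [0, 1] and are reproducible under an explicit seed.
#' @name classifiers
NULL

#' Train a classifier on a feature matrix
#'
#' @param X numeric feature matrix (rows = samples, named columns).
#' @param y labels: logical, or "positive"/"negative".
#' @param method `"RF"`, `"LR"`, `"SVM"` or `"GTB"`.
#' @param hyperparameters named list; recognized entries per method:
#'   RF `ntree` (500), `mtry` (sqrt of feature count); LR none;
#'   SVM `kernel` ("radial"), `cost` (1), `gamma`; GTB `nrounds` (100),
#'   `eta` (0.3), `max_depth` (6).
#' @param seed integer seed (default 42).
#' @return a `smorf_model` (classifier only; see [attach_model_context()] to
#'   bundle tables/schema/cutoffs for end-to-end prediction).
#' @export
train_classifier <- function(X, y, method = c("RF", "LR", "SVM", "GTB"),
                             hyperparameters = list(), seed = 42L) {
  method <- match.arg(method)
  truth <- as_logical_labels(y)
  if (length(unique(truth)) < 2L) stop("both classes must be present in y")
  stopifnot(nrow(X) == length(truth))
  X <- as.matrix(X)
  hp <- hyperparameters
  set.seed(as.integer(seed))
  yf <- factor(ifelse(truth, "positive", "negative"),
               levels = c("negative", "positive"))
  fit <- switch(method,
    RF = randomForest::randomForest(
      x = X, y = yf,
      ntree = hp$ntree %||% 500L,
      mtry = hp$mtry %||% max(1L, floor(sqrt(ncol(X))))
    ),
    LR = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      df$.y <- truth
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    SVM = e1071::svm(
      x = X, y = yf, probability = TRUE,
      kernel = hp$kernel %||% "radial",
      cost = hp$cost %||% 1,
      gamma = hp$gamma %||% (1 / ncol(X))
    ),
    GTB = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = hp$eta %||% 0.3,
                    max_depth = hp$max_depth %||% 6L,
                    seed = as.integer(seed),
                    nthread = 1L),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(truth)),
      nrounds = hp$nrounds %||% 100L,
      verbose = 0
    )
  )
  structure(list(
    method = method,
    hyperparameters = hp,
    fit = fit,
    feature_names = colnames(X),
    tables = NULL, schema = NULL, cutoffs = NULL,
    seed = as.integer(seed)
  ), class = "smorf_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a feature matrix with a trained classifier
#'
#' @param model a `smorf_model`.
#' @param X feature matrix with the model's feature columns.
#' @return numeric vector of positive-class scores in [0, 1].
#' @export
score_matrix <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(numeric(0L))
  if (!is.null(model$feature_names)) {
    X <- X[, model$feature_names, drop = FALSE]
  }
  scores <- switch(model$method,
    RF = predict(model$fit, X, type = "prob")[, "positive"],
    LR = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      as.numeric(predict(model$fit, newdata = df, type = "response"))
    },
    SVM = {
      p <- predict(model$fit, X, probability = TRUE)
      attr(p, "probabilities")[, "positive"]
    },
    GTB = as.numeric(predict(model$fit, X))
  )
  unname(pmin(pmax(scores, 0), 1))
}

#' Bundle a classifier with its encoding context
#'
#' @param model a `smorf_model` from [train_classifier()].
#' @param tables the [feature_tables] the model was trained with.
#' @param schema the [feature_schema] defining its input layout.
#' @param cutoffs optional per-start-codon cutoff map (see
#'   [default_cutoff_map()]).
#' @return the completed `smorf_model`.
#' @export
attach_model_context <- function(model, tables, schema, cutoffs = NULL) {
  model$tables <- tables
  model$schema <- schema
  model$cutoffs <- cutoffs
  model
}

#' Train an end-to-end smORF coding-potential model
#'
#' Fits feature tables on the training data, encodes it under `schema`,
#' trains the classifier and returns the complete bundle.
#'
#' @param pos_train,neg_train labelled `orf_dataset`s.
#' @inheritParams train_classifier
#' @param schema a [feature_schema] (default `"final32"`).
#' @param pseudocount smoothing for [fit_feature_tables()].
#' @param cutoffs per-start-codon cutoff map.
#' @return a complete `smorf_model`.
#' @export
train_smorf_model <- function(pos_train, neg_train, method = "RF",
                              hyperparameters = list(),
                              schema = feature_schema("final32"),
                              pseudocount = 1,
                              cutoffs = default_cutoff_map(),
                              seed = 42L) {
  tables <- fit_feature_tables(pos_train, neg_train, pseudocount)
  X <- rbind(encode_dataset(pos_train, tables, schema),
             encode_dataset(neg_train, tables, schema))
  y <- c(rep(TRUE, nrow(pos_train)), rep(FALSE, nrow(neg_train)))
  model <- train_classifier(X, y, method, hyperparameters, seed)
  attach_model_context(model, tables, schema, cutoffs)
}

#' Score ORF records with a complete model
#'
#' @param model a `smorf_model` carrying tables and schema.
#' @param dataset an `orf_dataset`.
#' @return numeric scores aligned with `dataset` rows.
#' @export
predict_scores <- function(model, dataset) {
  if (is.null(model$tables) || is.null(model$schema)) {
    stop("model has no feature tables/schema; use attach_model_context()")
  }
  if (nrow(dataset) == 0L) return(numeric(0L))
  X <- encode_dataset(dataset, model$tables, model$schema)
  score_matrix(model, X)
}

#' @export
print.smorf_model <- function(x, ...) {
  cat("<smorf_model> method=", x$method,
      " features=", length(x$feature_names),
      if (!is.null(x$schema)) paste0(" schema=", x$schema$name),
      if (!is.null(x$cutoffs)) paste0(" cutoffs=", length(x$cutoffs)),
      "\n", sep = "")
  invisible(x)
}

#' Save / load a model bundle
#'
#' The bundle (classifier state, feature tables, schema, cutoff map, seed) is
#' stored as a single RDS archive with a format/version stamp.
#'
#' @param model a `smorf_model`.
#' @param path file path (conventionally `.smorfcp.rds`).
#' @return `path` invisibly / the restored `smorf_model`.
#' @export
write_model <- function(model, path) {
  saveRDS(list(format = "smorfcp_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- readRDS(path)
  if (!identical(doc$format, "smorfcp_model")) {
    stop("not a smorfcp model bundle: ", path)
  }
  doc$model
}
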