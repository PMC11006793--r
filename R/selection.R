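#' @title Feature selection
#' @description
#' Two complementary routes shrink the 1169-dim complete feature vector to a
#' compact model input: stepwise component ablation (drop whole feature
#' blocks whose removal costs nothing) and mRMR ranking followed by
#' incremental feature selection (IFS) over the remaining individual
#' features. A final utility calibrates a precision-targeted decision
#' threshold from held-out scores.
#' @name selection
NULL

#' Stepwise leave-one-component-out feature ablation
#'
#' At each round every leave-one-component-out subset of the currently
#' retained components is cross-validated; the component whose removal yields
#' the best-performing subset (highest mean MCC, ties by higher ACC, then by
#' component name) is permanently dropped. Repeats until `stop_size`
#' components remain.
#'
#' @param pos_train,neg_train `orf_dataset`s.
#' @param components character vector of component names (subset of the
#'   complete schema's components); default all 15.
#' @param stop_size stop when this many components remain (default 1).
#' @param method,hyperparameters,k,seed,pseudocount CV configuration, see
#'   [cross_validate()].
#' @return an `ablation_trace` data.frame: one row per removal step with
#'   `removed_component`, `remaining` (comma-joined), `ACC`, `MCC` of the
#'   retained subset.
#' @export
ablate_components <- function(pos_train, neg_train,
                              components = names(COMPONENT_DIMS),
                              stop_size = 1L, method = "RF",
                              hyperparameters = list(), k = 10L,
                              seed = 42L, pseudocount = 1) {
  stopifnot(length(components) >= 2L)
  remaining <- components
  steps <- list()
  while (length(remaining) > stop_size) {
    evals <- lapply(seq_along(remaining), function(i) {
      sub <- remaining[-i]
      sch <- component_subset_schema(sub)
      cv <- cross_validate(pos_train, neg_train, method, hyperparameters,
                           schema = sch, k = k, seed = seed,
                           pseudocount = pseudocount)
      list(removed = remaining[i], ACC = cv$mean$ACC, MCC = cv$mean$MCC)
    })
    mcc <- vapply(evals, `[[`, numeric(1L), "MCC")
    acc <- vapply(evals, `[[`, numeric(1L), "ACC")
    rem <- vapply(evals, `[[`, character(1L), "removed")
    best <- order(-mcc, -acc, rem)[1L]
    remaining <- remaining[remaining != rem[best]]
    steps[[length(steps) + 1L]] <- data.frame(
      removed_component = rem[best],
      remaining = paste(remaining, collapse = ","),
      ACC = acc[best], MCC = mcc[best],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, steps)
  class(out) <- c("ablation_trace", "data.frame")
  out
}

component_subset_schema <- function(components) {
  structure(list(
    name = paste0("subset_", length(components)),
    components = data.frame(component = components,
                            dim = unname(COMPONENT_DIMS[components]),
                            stringsAsFactors = FALSE),
    feature_names = unlist(lapply(components, component_feature_names),
                           use.names = FALSE)
  ), class = "feature_schema")
}

#' mRMR feature ranking (mutual information quotient scheme)
#'
#' Features are discretized into three bins at mean +/- one standard
#' deviation (classic mRMR practice; constant features fall into one bin and
#' carry zero mutual information). Relevance MI(feature; label) is screened
#' with a G-test: on N samples, 2N times the plug-in MI is asymptotically
#' chi-square with (bins-1)(classes-1) degrees of freedom under
#' independence, and features not significant at `alpha` get relevance 0 —
#' without this screen, the tiny-MI/tiny-MI quotients of uninformative
#' features are numerically unstable and can outrank genuinely informative
#' but mutually redundant features. The first selected feature maximizes
#' screened relevance; each subsequent feature maximizes the quotient
#' relevance / mean MI(feature; already-selected). MI is in nats; ties break
#' by ascending feature name.
#'
#' @param X feature matrix with named columns.
#' @param y labels.
#' @param n_bins number of discretization bins (only 3, the mean +/- sd
#'   scheme, is currently supported).
#' @param alpha significance level of the relevance screen (default 0.001).
#' @return character vector: all feature names in rank order.
#' @export
mrmr_rank <- function(X, y, n_bins = 3L, alpha = 0.001) {
  stopifnot(ncol(X) >= 2L, n_bins == 3L)
  truth <- as_logical_labels(y)
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  X <- as.matrix(X)
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(X)))
  n <- length(truth)
  disc <- apply(X, 2L, discretize_msd)
  y_disc <- as.integer(truth) + 1L
  relevance <- vapply(seq_len(ncol(X)), function(j) {
    m <- mutual_information(disc[, j], y_disc)
    df <- (length(unique(disc[, j])) - 1L) *
      (length(unique(y_disc)) - 1L)
    if (df < 1L || 2 * n * m <= stats::qchisq(1 - alpha, df)) 0 else m
  }, numeric(1L))
  names(relevance) <- feats
  selected <- character(0L)
  candidates <- feats
  # cache pairwise MI between features as needed
  mi_cache <- matrix(NA_real_, ncol(X), ncol(X), dimnames = list(feats, feats))
  pair_mi <- function(a, b) {
    if (is.na(mi_cache[a, b])) {
      v <- mutual_information(disc[, a], disc[, b])
      mi_cache[a, b] <<- v
      mi_cache[b, a] <<- v
    }
    mi_cache[a, b]
  }
  while (length(candidates) > 0L) {
    if (length(selected) == 0L) {
      score <- relevance[candidates]
    } else {
      score <- vapply(candidates, function(f) {
        if (relevance[f] == 0) return(0)
        red <- mean(vapply(selected, function(s) pair_mi(f, s), numeric(1L)))
        if (red <= 0) Inf else relevance[f] / red
      }, numeric(1L))
    }
    best <- candidates[order(-score, candidates)[1L]]
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  selected
}

# 3 bins at mean +/- one standard deviation
discretize_msd <- function(v) {
  m <- mean(v)
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(rep.int(1L, length(v)))
  findInterval(v, c(m - s, m + s)) + 1L
}

# MI in nats between two integer-coded discrete vectors
mutual_information <- function(a, b) {
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  expected <- outer(pa, pb)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / expected[nz]))
}

#' Incremental feature selection over a ranking
#'
#' For each i in 1..n, cross-validates the model restricted to the top-i
#' ranked features (with the same seed, so fold assignment is shared across
#' subset sizes and the curve reflects feature content only) and records
#' ACC, MCC and the standard error of the fold MCCs.
#'
#' `best_size` follows the one-standard-error parsimony rule familiar from
#' penalized-regression tuning: the smallest subset whose mean MCC is within
#' one standard error of the best mean MCC. Once the informative features
#' are in, further additions move the CV estimate only within its own noise,
#' so a strict argmax drifts arbitrarily deep into that plateau;
#' `rule = "max"` restores the strict argmax (ties toward the smaller
#' subset).
#'
#' Supply either `pos_train`/`neg_train` (features re-encoded per fold from
#' re-fitted tables, ranked names must come from the `"reduced33"` layout) or
#' a precomputed matrix `X` with labels `y`.
#'
#' @param ranked_features character vector in rank order.
#' @param pos_train,neg_train `orf_dataset`s (dataset route).
#' @param X,y feature matrix and labels (matrix route).
#' @param method,hyperparameters,k,seed,pseudocount CV configuration.
#' @param rule `"one_se"` (default) or `"max"`.
#' @return a `ranking_result` list: `ranked_features`, `ifs_curve`
#'   (data.frame `subset_size`, `ACC`, `MCC`, `MCC_se`), `best_size`.
#' @export
ifs_select <- function(ranked_features, pos_train = NULL, neg_train = NULL,
                       X = NULL, y = NULL, method = "RF",
                       hyperparameters = list(), k = 10L, seed = 42L,
                       pseudocount = 1, rule = c("one_se", "max")) {
  rule <- match.arg(rule)
  n <- length(ranked_features)
  stopifnot(n >= 1L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    top <- ranked_features[seq_len(i)]
    cv <- if (!is.null(X)) {
      cross_validate_matrix(as.matrix(X)[, top, drop = FALSE], y,
                            method, hyperparameters, k = k, seed = seed)
    } else {
      cross_validate(pos_train, neg_train, method, hyperparameters,
                     schema = feature_schema_from_features(top),
                     k = k, seed = seed, pseudocount = pseudocount)
    }
    fold_mcc <- vapply(cv$folds, `[[`, numeric(1L), "MCC")
    rows[[i]] <- data.frame(subset_size = i, ACC = cv$mean$ACC,
                            MCC = cv$mean$MCC,
                            MCC_se = sd(fold_mcc) / sqrt(length(fold_mcc)))
  }
  curve <- do.call(rbind, rows)
  i_max <- order(-curve$MCC, curve$subset_size)[1L]
  best_size <- if (rule == "max") {
    curve$subset_size[i_max]
  } else {
    min(curve$subset_size[curve$MCC >= curve$MCC[i_max] -
                            curve$MCC_se[i_max]])
  }
  structure(list(ranked_features = ranked_features,
                 ifs_curve = curve,
                 best_size = best_size,
                 rule = rule),
            class = "ranking_result")
}

#' Precision-targeted score cutoff
#'
#' Returns the smallest candidate threshold (distinct scores plus the
#' boundaries 0 and 1) at which precision over the supplied labelled scores
#' reaches `target_precision` with at least one predicted positive. When no
#' threshold qualifies, returns 1.0 — "reject every candidate", the behaviour
#' used to exclude start codons whose score distribution cannot reach the
#' precision target.
#'
#' @param scores held-out scores in [0, 1].
#' @param labels labels; both classes must be present.
#' @param target_precision required precision in (0, 1].
#' @return cutoff in [0, 1].
#' @export
choose_cutoff <- function(scores, labels, target_precision) {
  stopifnot(target_precision > 0, target_precision <= 1)
  truth <- as_logical_labels(labels)
  if (!any(truth) || all(truth)) stop("both classes must be present")
  for (th in sort(unique(c(0, scores, 1)))) {
    cm <- confusion(scores, truth, th)
    if (cm[["TP"]] + cm[["FP"]] == 0L) next
    if (cm[["TP"]] / (cm[["TP"]] + cm[["FP"]]) >= target_precision) return(th)
  }
  1.0
}
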