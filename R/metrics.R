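#' @title Binary classification metrics
#' @description
#' The metric set used throughout the package: sensitivity (SN), specificity
#' (SP), precision (PRE), accuracy (ACC), F1 score (F1S), the harmonic mean
#' of SN and SP (HM), and Matthews correlation coefficient (MCC), plus
#' trapezoid ROC/PR AUC. Undefined 0/0 rates are reported as 0 (flagged), and
#' a zero MCC denominator yields MCC 0, so cross-validation averages stay
#' total.
#' @name metrics
NULL

#' Confusion counts at a score cutoff
#'
#' A sample is predicted positive when `score >= cutoff` (ties positive).
#'
#' @param scores numeric scores in [0, 1].
#' @param labels logical or "positive"/"negative" vector.
#' @param cutoff decision threshold in [0, 1].
#' @return named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion <- function(scores, labels, cutoff = 0.5) {
  stopifnot(cutoff >= 0, cutoff <= 1, length(scores) == length(labels))
  truth <- as_logical_labels(labels)
  pred <- scores >= cutoff
  c(TP = sum(pred & truth), TN = sum(!pred & !truth),
    FP = sum(pred & !truth), FN = sum(!pred & truth))
}

as_logical_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels == "positive"
}

#' Compute rate metrics from confusion counts
#'
#' @param TP,TN,FP,FN non-negative counts (or a single named vector as
#'   returned by [confusion()] passed as `TP`).
#' @return list with counts, SN, SP, PRE, ACC, F1S, HM, MCC and a
#'   `undefined` character vector naming any 0/0 rates reported as 0.
#' @export
compute_metrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.null(TN) && length(TP) == 4L) {
    TN <- TP[["TN"]]; FP <- TP[["FP"]]; FN <- TP[["FN"]]; TP <- TP[["TP"]]
  }
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  total <- TP + TN + FP + FN
  if (total == 0) stop("all confusion counts are zero")
  undefined <- character(0L)
  rate <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  sn <- rate(TP, TP + FN, "SN")
  sp <- rate(TN, TN + FP, "SP")
  pre <- rate(TP, TP + FP, "PRE")
  acc <- (TP + TN) / total
  f1s <- rate(2 * pre * sn, pre + sn, "F1S")
  hm <- rate(2 * sp * sn, sp + sn, "HM")
  denom <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  mcc <- if (denom == 0) {
    undefined <- c(undefined, "MCC")
    0
  } else {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / denom
  }
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       SN = sn, SP = sp, PRE = pre, ACC = acc, F1S = f1s, HM = hm,
       MCC = mcc, undefined = undefined)
}

#' ROC or precision-recall curve with trapezoid AUC
#'
#' Thresholds sweep all distinct scores plus the boundaries 0 and 1 (scores
#' at the threshold count as positive). ROC plots FPR against TPR; PR plots
#' recall (SN) against precision (PRE), and its AUC integrates precision over
#' recall.
#'
#' @param scores numeric scores in [0, 1].
#' @param labels see [confusion()]; both classes must be present.
#' @param kind `"roc"` or `"pr"`.
#' @return list with `curve` (data.frame `threshold`, `x`, `y`) and `auc`.
#' @export
curve_and_auc <- function(scores, labels, kind = c("roc", "pr")) {
  kind <- match.arg(kind)
  truth <- as_logical_labels(labels)
  if (!any(truth) || all(truth)) stop("both classes must be present")
  thresholds <- sort(unique(c(0, scores, 1)), decreasing = FALSE)
  pts <- t(vapply(thresholds, function(th) {
    cm <- confusion(scores, truth, th)
    m <- compute_metrics(cm)
    if (kind == "roc") {
      c(x = 1 - m$SP, y = m$SN, ok = 1)
    } else {
      # PRE is undefined where nothing is predicted positive; those
      # thresholds contribute no PR point
      c(x = m$SN, y = m$PRE, ok = as.numeric(!("PRE" %in% m$undefined)))
    }
  }, c(x = 0, y = 0, ok = 1)))
  keep <- pts[, "ok"] > 0
  # descending threshold order: x (FPR or recall) is then non-decreasing,
  # which is the correct sweep for trapezoid integration
  ord <- order(thresholds[keep], decreasing = TRUE)
  curve <- data.frame(threshold = thresholds[keep][ord],
                      x = pts[keep, "x"][ord], y = pts[keep, "y"][ord])
  if (kind == "roc" && (curve$x[1L] > 0 || curve$y[1L] > 0)) {
    # scores tied at 1 leave predictions at the top threshold; anchor the
    # sweep at the empty-prediction origin
    curve <- rbind(data.frame(threshold = NA_real_, x = 0, y = 0), curve)
  }
  if (kind == "pr" && nrow(curve) > 0L && curve$x[1L] > 0) {
    # anchor recall 0 at the precision of the smallest attained recall
    curve <- rbind(data.frame(threshold = NA_real_, x = 0, y = curve$y[1L]),
                   curve)
  }
  auc <- sum(diff(curve$x) *
               (head(curve$y, -1L) + tail(curve$y, -1L)) / 2)
  list(curve = curve, auc = auc)
}
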