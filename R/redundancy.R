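#' Greedy redundancy removal by global-alignment identity
#'
#' Mirrors the classic cluster-at-90%-identity preprocessing step used when
#' assembling sequence training sets: records are visited longest-first
#' (ties by id, lexicographic) and a record is dropped when its
#' global-alignment identity to an already-retained representative is at
#' least `identity` AND the shorter/longer length ratio is at least
#' `length_ratio`. Identity is the proportion of matching positions over the
#' global alignment length (gaps included), computed on
#' `upstream3 + orf_seq`.
#'
#' @param dataset an `orf_dataset`.
#' @param identity identity threshold in (0, 1].
#' @param length_ratio length-ratio threshold in (0, 1].
#' @return the retained subset, original row order preserved.
#' @export
remove_redundancy <- function(dataset, identity = 0.9, length_ratio = 0.9) {
  stopifnot(identity > 0, identity <= 1, length_ratio > 0, length_ratio <= 1)
  if (nrow(dataset) <= 1L) return(dataset)
  seqs <- paste0(dataset$upstream3, dataset$orf_seq)
  lens <- nchar(seqs)
  ord <- order(-lens, dataset$id)
  keep_idx <- integer(0L)
  for (i in ord) {
    redundant <- FALSE
    for (j in keep_idx) {
      lr <- min(lens[i], lens[j]) / max(lens[i], lens[j])
      if (lr < length_ratio) next
      if (alignment_identity(seqs[i], seqs[j]) >= identity) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep_idx <- c(keep_idx, i)
  }
  dataset[sort(keep_idx), , drop = FALSE]
}

#' Global-alignment identity between two nucleotide strings
#'
#' Needleman-Wunsch global alignment (Biostrings defaults with a simple
#' match/mismatch scheme); identity = matches / alignment length including
#' gap columns.
#'
#' @param a,b nucleotide strings.
#' @return identity fraction in [0, 1].
#' @export
alignment_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE
    ),
    gapOpening = 5, gapExtension = 2
  )
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Drop test records redundant with a training set
#'
#' Cross-split counterpart of [remove_redundancy()]: every test record whose
#' identity to ANY training record reaches the thresholds is removed, so no
#' near-duplicate of a training sequence leaks into the evaluation split.
#'
#' @param train,test `orf_dataset`s.
#' @inheritParams remove_redundancy
#' @return the filtered test set.
#' @export
remove_cross_redundancy <- function(train, test,
                                    identity = 0.9, length_ratio = 0.9) {
  if (nrow(test) == 0L || nrow(train) == 0L) return(test)
  tr <- paste0(train$upstream3, train$orf_seq)
  te <- paste0(test$upstream3, test$orf_seq)
  ltr <- nchar(tr); lte <- nchar(te)
  keep <- vapply(seq_along(te), function(i) {
    for (j in seq_along(tr)) {
      lr <- min(lte[i], ltr[j]) / max(lte[i], ltr[j])
      if (lr < length_ratio) next
      if (alignment_identity(te[i], tr[j]) >= identity) return(FALSE)
    }
    TRUE
  }, logical(1L))
  test[keep, , drop = FALSE]
}

#' Assemble balanced train/test splits from positive and negative sets
#'
#' Optionally downsamples the negative set to the positive count, then splits
#' each label 2:1 into train and test (per-label, reproducible under `seed`),
#' and finally removes test records redundant with the training split at the
#' same thresholds used for within-set redundancy removal.
#'
#' @param pos,neg `orf_dataset`s labelled positive / negative.
#' @param seed integer seed controlling downsampling and the split.
#' @param train_fraction fraction of each label assigned to training.
#' @param balance if `TRUE`, randomly downsample the larger label to the
#'   smaller one's count before splitting.
#' @param identity,length_ratio cross-split redundancy thresholds.
#' @return `list(train =, test =)` of `orf_dataset`s.
#' @export
assemble_datasets <- function(pos, neg, seed = 42L, train_fraction = 2 / 3,
                              balance = TRUE,
                              identity = 0.9, length_ratio = 0.9) {
  if (nrow(pos) < 10L || nrow(neg) < 10L) {
    stop("need at least 10 records per label to support 10-fold CV")
  }
  pos$label <- "positive"
  neg$label <- "negative"
  set.seed(as.integer(seed))
  if (balance) {
    n <- min(nrow(pos), nrow(neg))
    if (nrow(pos) > n) pos <- pos[sort(sample.int(nrow(pos), n)), , drop = FALSE]
    if (nrow(neg) > n) neg <- neg[sort(sample.int(nrow(neg), n)), , drop = FALSE]
  }
  split_one <- function(d) {
    n <- nrow(d)
    n_train <- floor(n * train_fraction)
    idx <- sample.int(n)
    list(train = d[sort(idx[seq_len(n_train)]), , drop = FALSE],
         test = d[sort(idx[-seq_len(n_train)]), , drop = FALSE])
  }
  sp <- split_one(pos)
  sn <- split_one(neg)
  train <- rbind(sp$train, sn$train)
  test <- rbind(sp$test, sn$test)
  test <- remove_cross_redundancy(train, test, identity, length_ratio)
  class(train) <- class(test) <- c("orf_dataset", "data.frame")
  attr(train, "split_tag") <- "train"
  attr(test, "split_tag") <- "test"
  list(train = train, test = test)
}
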