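#' @title Class-conditional probability tables for feature encoding
#' @description
#' Three pairs of tables are fitted from positive (mRNA smORF) and negative
#' (ncRNA ORF) training sequences and parameterize the log-ratio encoders:
#'
#' * **site probabilities** — P(nucleotide x at TIS site i) for
#'   i in \{-3, -2, -1, 4, 5, 6\}, i.e. the three upstream bases and the
#'   first codon after the start codon (ORF positions 4-6);
#' * **codon usage** — codon count divided by the count of its encoding
#'   amino acid (the three stop codons form one class), the classical
#'   synonymous-codon usage bias;
#' * **hexamer frequencies** — relative frequencies of the 4096 in-frame
#'   hexamers (read at ORF positions 1, 4, 7, ... stepping one codon).
#'
#' All counts receive additive (pseudocount) smoothing before normalization
#' so every stored probability is strictly positive and every log ratio is
#' finite, including for codons or hexamers absent from training data.
#' @name feature_tables
NULL

TIS_SITES <- c("-3", "-2", "-1", "4", "5", "6")
DNA_BASES <- c("A", "C", "G", "T")

all_kmers <- function(k) {
  Biostrings::mkAllStrings(DNA_BASES, k)
}

#' Fit feature tables from positive and negative training sets
#'
#' @param pos_train,neg_train non-empty `orf_dataset`s.
#' @param pseudocount additive smoothing added to every count cell before
#'   normalization (default 1).
#' @return a `feature_tables` list with elements `site_prob_pos`,
#'   `site_prob_neg` (4 x 6 matrices, rows A/C/G/T, columns -3..-1,4..6),
#'   `codon_usage_pos`, `codon_usage_neg` (named 64-vectors),
#'   `hexamer_freq_pos`, `hexamer_freq_neg` (named 4096-vectors).
#' @export
fit_feature_tables <- function(pos_train, neg_train, pseudocount = 1) {
  if (nrow(pos_train) == 0L || nrow(neg_train) == 0L) {
    stop("both training datasets must be non-empty")
  }
  structure(list(
    site_prob_pos = fit_site_probs(pos_train, pseudocount),
    site_prob_neg = fit_site_probs(neg_train, pseudocount),
    codon_usage_pos = fit_codon_usage(pos_train, pseudocount),
    codon_usage_neg = fit_codon_usage(neg_train, pseudocount),
    hexamer_freq_pos = fit_hexamer_freq(pos_train, pseudocount),
    hexamer_freq_neg = fit_hexamer_freq(neg_train, pseudocount),
    pseudocount = pseudocount
  ), class = "feature_tables")
}

fit_site_probs <- function(dataset, pseudocount) {
  m <- matrix(0, nrow = 4L, ncol = 6L,
              dimnames = list(DNA_BASES, TIS_SITES))
  chars <- cbind(
    substr(dataset$upstream3, 1L, 1L),
    substr(dataset$upstream3, 2L, 2L),
    substr(dataset$upstream3, 3L, 3L),
    substr(dataset$orf_seq, 4L, 4L),
    substr(dataset$orf_seq, 5L, 5L),
    substr(dataset$orf_seq, 6L, 6L)
  )
  for (j in 1:6) {
    tab <- table(factor(chars[, j], levels = DNA_BASES))
    m[, j] <- as.numeric(tab)
  }
  sweep(m + pseudocount, 2L, colSums(m) + 4 * pseudocount, "/")
}

fit_codon_usage <- function(dataset, pseudocount) {
  codons <- all_kmers(3L)
  counts <- setNames(numeric(64L), codons)
  obs <- unlist(lapply(dataset$orf_seq, codon_split), use.names = FALSE)
  tab <- table(factor(obs[obs %in% codons], levels = codons))
  counts[] <- as.numeric(tab)
  aa <- codon_amino_classes()
  usage <- counts
  for (cls in unique(aa)) {
    members <- names(aa)[aa == cls]
    usage[members] <- (counts[members] + pseudocount) /
      (sum(counts[members]) + pseudocount * length(members))
  }
  usage
}

# codon -> amino-acid class, with the three stop codons as one class "*"
codon_amino_classes <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))[all_kmers(3L)]
}

inframe_hexamers <- function(orf_seq) {
  n <- nchar(orf_seq)
  if (n < 6L) return(character(0L))
  starts <- seq(1L, n - 5L, by = 3L)
  substring(orf_seq, starts, starts + 5L)
}

fit_hexamer_freq <- function(dataset, pseudocount) {
  hexamers <- all_kmers(6L)
  obs <- unlist(lapply(dataset$orf_seq, inframe_hexamers), use.names = FALSE)
  obs <- obs[!grepl("N", obs, fixed = TRUE)]
  tab <- table(factor(obs, levels = hexamers))
  counts <- as.numeric(tab)
  setNames((counts + pseudocount) / (sum(counts) + pseudocount * 4096),
           hexamers)
}

#' Serialize feature tables to a versioned JSON document
#' @param tables a `feature_tables` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tables <- function(tables, path) {
  doc <- list(
    format = "smorfcp_feature_tables",
    version = 1L,
    pseudocount = tables$pseudocount,
    site_prob_pos = as.data.frame(tables$site_prob_pos),
    site_prob_neg = as.data.frame(tables$site_prob_neg),
    codon_usage_pos = as.list(tables$codon_usage_pos),
    codon_usage_neg = as.list(tables$codon_usage_neg),
    hexamer_freq_pos = as.list(tables$hexamer_freq_pos),
    hexamer_freq_neg = as.list(tables$hexamer_freq_neg)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read feature tables from JSON
#' @param path a file written by [write_feature_tables()].
#' @return a `feature_tables` object.
#' @export
read_feature_tables <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "smorfcp_feature_tables")) {
    stop("not a smorfcp feature-tables document: ", path)
  }
  as_mat <- function(df) {
    m <- as.matrix(df)
    rownames(m) <- DNA_BASES
    colnames(m) <- TIS_SITES
    m
  }
  structure(list(
    site_prob_pos = as_mat(doc$site_prob_pos),
    site_prob_neg = as_mat(doc$site_prob_neg),
    codon_usage_pos = unlist(doc$codon_usage_pos),
    codon_usage_neg = unlist(doc$codon_usage_neg),
    hexamer_freq_pos = unlist(doc$hexamer_freq_pos),
    hexamer_freq_neg = unlist(doc$hexamer_freq_neg),
    pseudocount = doc$pseudocount
  ), class = "feature_tables")
}
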