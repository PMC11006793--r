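#' @title Sequence feature encoders
#' @description
#' Encoders turn one ORF record (upstream context + ORF) into the numeric
#' features of a [feature_schema]. Log-ratio features (nucleotide bias,
#' codon bias, hexamer score) use the natural logarithm of
#' positive/negative table probabilities; ambiguous bases (`N`) contribute a
#' log ratio of 0 (equivalently, probability 0.25 in both classes at a TIS
#' site). Frequency features are relative frequencies over valid
#' (`N`-free) windows.
#' @name encoders
NULL

#' Translation-initiation-site nucleotide bias
#'
#' For each of the six TIS sites (-3, -2, -1 from the upstream context; 4, 5,
#' 6 = the codon after the start codon), the natural log ratio of the
#' positive to negative class probability of the observed nucleotide.
#'
#' @param upstream3 3-letter upstream context.
#' @param orf_seq ORF sequence (start codon first).
#' @param tables fitted [feature_tables].
#' @return named 6-vector in site order (-3, -2, -1, 4, 5, 6).
#' @export
nucleotide_bias <- function(upstream3, orf_seq, tables) {
  obs <- c(
    substr(upstream3, 1L, 1L), substr(upstream3, 2L, 2L),
    substr(upstream3, 3L, 3L),
    substr(orf_seq, 4L, 4L), substr(orf_seq, 5L, 5L), substr(orf_seq, 6L, 6L)
  )
  out <- numeric(6L)
  for (j in 1:6) {
    x <- obs[j]
    out[j] <- if (x %in% DNA_BASES) {
      log(tables$site_prob_pos[x, j] / tables$site_prob_neg[x, j])
    } else 0
  }
  names(out) <- paste0("nb_", TIS_SITES)
  out
}

#' Codon usage bias score
#'
#' Mean over all ORF codons (stop codon included) of the natural log ratio of
#' positive to negative synonymous-codon usage. Being a mean, the score does
#' not scale with ORF length.
#'
#' @inheritParams nucleotide_bias
#' @return scalar.
#' @export
codon_bias <- function(orf_seq, tables) {
  cods <- codon_split(orf_seq)
  if (length(cods) == 0L) return(0)
  idx <- match(cods, names(tables$codon_usage_pos))
  ratios <- ifelse(is.na(idx), 0,
                   log(tables$codon_usage_pos[idx] /
                         tables$codon_usage_neg[idx]))
  sum(ratios) / length(cods)
}

#' In-frame hexamer log-likelihood score
#'
#' Sum over the ORF's in-frame hexamers (positions 1, 4, 7, ... stepping one
#' codon) of the natural log ratio of positive to negative hexamer frequency.
#' A sum, not a mean: the score deliberately grows with ORF length, which is
#' itself informative for coding potential.
#'
#' @inheritParams nucleotide_bias
#' @return scalar; 0 with a warning for sequences shorter than 6 nt.
#' @export
hexamer_score <- function(orf_seq, tables) {
  if (nchar(orf_seq) < 6L) {
    warning("sequence shorter than 6 nt has no hexamers; score 0")
    return(0)
  }
  hx <- inframe_hexamers(orf_seq)
  idx <- match(hx, names(tables$hexamer_freq_pos))
  ratios <- ifelse(is.na(idx), 0,
                   log(tables$hexamer_freq_pos[idx] /
                         tables$hexamer_freq_neg[idx]))
  sum(ratios)
}

#' Fickett position parameters
#'
#' For each nucleotide, the asymmetry of its counts across the three codon
#' positions: `max(b1, b2, b3) / (min(b1, b2, b3) + 1)`. Coding sequence
#' shows strong periodicity (high values); random sequence does not. Returned
#' in the order T, A, C, G.
#'
#' @inheritParams nucleotide_bias
#' @return named 4-vector (T, A, C, G).
#' @export
fickett_scores <- function(orf_seq) {
  cods <- codon_split(orf_seq)
  pos_chars <- list(substr(cods, 1L, 1L), substr(cods, 2L, 2L),
                    substr(cods, 3L, 3L))
  out <- vapply(c("T", "A", "C", "G"), function(b) {
    counts <- vapply(pos_chars, function(ch) sum(ch == b), numeric(1L))
    max(counts) / (min(counts) + 1)
  }, numeric(1L))
  names(out) <- paste0("fickett_", c("T", "A", "C", "G"))
  out
}

#' Sliding-window k-mer relative frequencies
#'
#' @param orf_seq nucleotide string.
#' @param k word size (1-4).
#' @return named `4^k`-vector in lexicographic order, summing to 1 when at
#'   least one `N`-free window exists, all-zero otherwise.
#' @export
kmer_freq <- function(orf_seq, k) {
  stopifnot(k %in% 1:4)
  kmers <- all_kmers(k)
  n <- nchar(orf_seq)
  out <- setNames(numeric(length(kmers)), paste0("mer", k, "_", kmers))
  if (n < k) return(out)
  wins <- substring(orf_seq, 1:(n - k + 1L), k:n)
  idx <- match(wins, kmers)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(out)
  out[] <- tabulate(idx, nbins = length(kmers)) / length(idx)
  out
}

#' Gapped k-mer relative frequencies
#'
#' Discontinuous word features: `mode = "gap"` counts nucleotide pairs
#' separated by `g` unspecified bases (16 patterns); `mode = "bigap"` counts
#' dinucleotide pairs separated by `g` bases (256 patterns). Sliding step 1;
#' windows containing `N` in a specified position are skipped; frequencies
#' normalized to sum 1.
#'
#' @param orf_seq nucleotide string.
#' @param g gap width (1-3).
#' @param mode `"gap"` or `"bigap"`.
#' @return named 16- or 256-vector; all-zero when the sequence is shorter
#'   than the pattern span.
#' @export
gap_freq <- function(orf_seq, g, mode = c("gap", "bigap")) {
  mode <- match.arg(mode)
  stopifnot(g %in% 1:3)
  k <- if (mode == "gap") 1L else 2L
  span <- 2L * k + g
  pat_names <- gap_pattern_names(g, mode)
  out <- setNames(numeric(length(pat_names)), pat_names)
  n <- nchar(orf_seq)
  if (n < span) return(out)
  starts <- 1:(n - span + 1L)
  left <- substring(orf_seq, starts, starts + k - 1L)
  right <- substring(orf_seq, starts + k + g, starts + 2L * k + g - 1L)
  units <- all_kmers(k)
  li <- match(left, units)
  ri <- match(right, units)
  valid <- !is.na(li) & !is.na(ri)
  if (!any(valid)) return(out)
  idx <- (li[valid] - 1L) * length(units) + ri[valid]
  out[] <- tabulate(idx, nbins = length(pat_names)) / sum(valid)
  out
}

# compute one named component vector for a record
encode_component <- function(component, upstream3, orf_seq, tables) {
  switch(component,
    orf_length = c(orf_length = nchar(orf_seq) / 3),
    mer1 = kmer_freq(orf_seq, 1L),
    mer2 = kmer_freq(orf_seq, 2L),
    mer3 = kmer_freq(orf_seq, 3L),
    mer4 = kmer_freq(orf_seq, 4L),
    nucleotide_bias = nucleotide_bias(upstream3, orf_seq, tables),
    hexamer_score = c(hexamer_score = hexamer_score(orf_seq, tables)),
    codon_bias = c(codon_bias = codon_bias(orf_seq, tables)),
    fickett = fickett_scores(orf_seq),
    gap1 = gap_freq(orf_seq, 1L, "gap"),
    gap2 = gap_freq(orf_seq, 2L, "gap"),
    gap3 = gap_freq(orf_seq, 3L, "gap"),
    bigap1 = gap_freq(orf_seq, 1L, "bigap"),
    bigap2 = gap_freq(orf_seq, 2L, "bigap"),
    bigap3 = gap_freq(orf_seq, 3L, "bigap"),
    stop("unknown feature component: ", component)
  )
}

#' Encode one ORF record into a feature vector
#'
#' Deterministically concatenates the schema's components. When the schema is
#' built from individual feature names (e.g. `"final32"`), the needed base
#' components are computed once and the named features selected in schema
#' order.
#'
#' @param upstream3,orf_seq the record's sequences.
#' @param tables fitted [feature_tables].
#' @param schema a [feature_schema].
#' @return named numeric vector of length `schema_dim(schema)`.
#' @export
encode_record <- function(upstream3, orf_seq, tables, schema) {
  comps <- schema$components$component
  if (all(comps %in% names(COMPONENT_DIMS))) {
    vec <- unlist(lapply(comps, encode_component,
                         upstream3 = upstream3, orf_seq = orf_seq,
                         tables = tables))
    return(vec)
  }
  # per-feature schema: compute each base component once, then pick
  base <- feature_component_of(comps)
  values <- unlist(lapply(unique(base), encode_component,
                          upstream3 = upstream3, orf_seq = orf_seq,
                          tables = tables))
  values[comps]
}

# map individual feature names to their base component
feature_component_of <- function(features) {
  vapply(features, function(f) {
    if (f %in% c("orf_length", "hexamer_score", "codon_bias")) return(f)
    if (startsWith(f, "mer1_")) return("mer1")
    if (startsWith(f, "mer2_")) return("mer2")
    if (startsWith(f, "mer3_")) return("mer3")
    if (startsWith(f, "mer4_")) return("mer4")
    if (startsWith(f, "nb_")) return("nucleotide_bias")
    if (startsWith(f, "fickett_")) return("fickett")
    if (startsWith(f, "gap")) return(substr(f, 1L, 4L))
    if (startsWith(f, "bigap")) return(substr(f, 1L, 6L))
    stop("unknown feature name: ", f)
  }, character(1L), USE.NAMES = FALSE)
}

#' Encode a dataset into a feature matrix
#'
#' @param dataset an `orf_dataset`.
#' @param tables fitted [feature_tables].
#' @param schema a [feature_schema].
#' @return numeric matrix, one row per record (rownames = ids), columns in
#'   schema order.
#' @export
encode_dataset <- function(dataset, tables, schema) {
  m <- matrix(0, nrow = nrow(dataset), ncol = schema_dim(schema),
              dimnames = list(dataset$id, schema$feature_names))
  for (i in seq_len(nrow(dataset))) {
    m[i, ] <- encode_record(dataset$upstream3[i], dataset$orf_seq[i],
                            tables, schema)
  }
  m
}
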