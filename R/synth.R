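#' @title Synthetic training sets and toy genomes
#' @description
#' Generators that emulate the contrast between coding smORFs and ncRNA ORFs
#' so the whole pipeline is testable without downloads. Positives are
#' sampled codon-wise from a skewed synonymous-codon distribution with a
#' Kozak-like upstream context (purine enriched at -3, G at ORF position 4);
#' negatives are uniform-codon ORFs with an ATG start. Both effects scale
#' with a strength in [0, 1]: at 0 the classes are exchangeable (a null
#' construction), at 1 they are strongly separable.
#' @name synth
NULL

#' Synthetic training-set configuration
#'
#' @param n_pos,n_neg records per class.
#' @param codon_bias_strength in [0, 1]: within each synonymous family, one
#'   codon receives weight `1 + 3 * strength` against 1 for the others.
#' @param tis_bias_strength in [0, 1]: P(A or G at site -3) and P(G at site
#'   4) are `0.25 + 0.5 * strength` each (A/G split evenly at -3).
#' @param length_range codon-count bounds (stop included), within [2, 101].
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_pos = 500L, n_neg = 500L,
                         codon_bias_strength = 1,
                         tis_bias_strength = 1,
                         length_range = c(11L, 101L), seed = 42L) {
  stopifnot(codon_bias_strength >= 0, codon_bias_strength <= 1,
            tis_bias_strength >= 0, tis_bias_strength <= 1,
            length(length_range) == 2L,
            length_range[1L] >= 2L, length_range[2L] <= 101L,
            length_range[1L] <= length_range[2L])
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 codon_bias_strength = codon_bias_strength,
                 tis_bias_strength = tis_bias_strength,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate synthetic positive/negative training sets
#'
#' @param cfg a [synth_config].
#' @return `list(pos =, neg =)` of labelled `orf_dataset`s; reproducible
#'   under `cfg$seed`.
#' @export
generate_training_sets <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  sense_codons <- setdiff(all_kmers(3L), STOP_CODONS)
  skew <- skewed_codon_weights(cfg$codon_bias_strength)
  pos <- sample_orf_set(cfg$n_pos, "pos", cfg$length_range,
                        internal_weights = skew[sense_codons],
                        stop_weights = skew[STOP_CODONS],
                        tis_strength = cfg$tis_bias_strength)
  neg <- sample_orf_set(cfg$n_neg, "neg", cfg$length_range,
                        internal_weights = setNames(
                          rep(1, length(sense_codons)), sense_codons),
                        stop_weights = setNames(rep(1, 3L), STOP_CODONS),
                        tis_strength = 0)
  list(
    pos = orf_dataset(pos$id, pos$upstream3, pos$orf_seq,
                      label = "positive", source = "synthetic",
                      validate = FALSE),
    neg = orf_dataset(neg$id, neg$upstream3, neg$orf_seq,
                      label = "negative", source = "synthetic",
                      validate = FALSE)
  )
}

# within each synonymous family (stops are one family), the lexicographically
# first codon gets weight 1 + 3*strength, the rest 1
skewed_codon_weights <- function(strength) {
  aa <- codon_amino_classes()
  w <- setNames(rep(1, 64L), names(aa))
  for (cls in unique(aa)) {
    members <- sort(names(aa)[aa == cls])
    w[members[1L]] <- 1 + 3 * strength
  }
  w
}

sample_orf_set <- function(n, prefix, length_range,
                           internal_weights, stop_weights, tis_strength) {
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  internal <- names(internal_weights)
  stops <- names(stop_weights)
  orf_seq <- vapply(lens, function(len) {
    body <- sample(internal, len - 2L, replace = TRUE,
                   prob = internal_weights)
    stop_c <- sample(stops, 1L, prob = stop_weights)
    paste0("ATG", paste(body, collapse = ""), stop_c)
  }, character(1L))
  if (tis_strength > 0) {
    # enrich G at ORF site 4 (first base of codon 2) by resampling codon 2
    # from G-initial codons with the boosted probability
    g_codons <- internal[startsWith(internal, "G")]
    p_g <- 0.25 + 0.5 * tis_strength
    swap <- runif(length(orf_seq)) < p_g
    repl <- sample(g_codons, sum(swap), replace = TRUE,
                   prob = internal_weights[g_codons])
    substr(orf_seq[swap], 4L, 6L) <- repl
  }
  upstream3 <- vapply(seq_len(length(orf_seq)), function(i) {
    m3 <- sample_site(c("A", "G"), tis_strength)
    paste0(m3, sample(DNA_BASES, 1L), sample(DNA_BASES, 1L))
  }, character(1L))
  list(id = sprintf("%s_%05d", prefix, seq_len(length(orf_seq))),
       upstream3 = upstream3, orf_seq = orf_seq)
}

# one base: enriched set gets total probability 0.25*|set| + 0.5*strength,
# split evenly; remaining mass split over the other bases
sample_site <- function(enriched, strength) {
  p <- setNames(rep(0.25, 4L), DNA_BASES)
  boost <- 0.5 * strength
  p[enriched] <- p[enriched] + boost / length(enriched)
  p[setdiff(DNA_BASES, enriched)] <-
    p[setdiff(DNA_BASES, enriched)] - boost / (4 - length(enriched))
  sample(DNA_BASES, 1L, prob = p)
}

#' Generate a labelled synthetic feature matrix
#'
#' Utility for exercising feature ranking: `n_informative` features are
#' shifted by `effect` standard deviations between classes, the rest are
#' independent standard-normal noise. Informative features are named
#' `inf_1`, `inf_2`, ...; noise features `noise_1`, ... Columns are shuffled
#' so position carries no information.
#'
#' @param n_per_class samples per class.
#' @param n_informative,n_noise feature counts.
#' @param effect between-class mean shift in SD units (default 2).
#' @param seed integer seed.
#' @return list `X` (matrix), `y` (logical), `informative` (names).
#' @export
generate_feature_matrix <- function(n_per_class = 500L, n_informative = 2L,
                                    n_noise = 8L, effect = 2, seed = 42L) {
  set.seed(as.integer(seed))
  n <- 2L * n_per_class
  y <- rep(c(TRUE, FALSE), each = n_per_class)
  p <- n_informative + n_noise
  X <- matrix(rnorm(n * p), nrow = n, ncol = p)
  for (j in seq_len(n_informative)) {
    X[y, j] <- X[y, j] + effect
  }
  colnames(X) <- c(paste0("inf_", seq_len(n_informative)),
                   paste0("noise_", seq_len(n_noise)))
  perm <- sample.int(p)
  X <- X[, perm, drop = FALSE]
  list(X = X, y = y,
       informative = paste0("inf_", seq_len(n_informative)))
}

#' Generate a toy genome with planted smORFs
#'
#' Contig backgrounds are uniform random sequence; each planted ORF (a start
#' codon, a codon count and a strand) is built without internal in-frame
#' stops and overwritten onto a free location, so planted intervals are
#' guaranteed to be recovered by the scanner. A configurable subset of the
#' planted ORFs is covered by decoy CDS features in the emitted GFF3 to
#' exercise CDS-containment filtering.
#'
#' @param n_contigs number of contigs.
#' @param contig_len contig length (nt).
#' @param planted data.frame with columns `start_codon`, `codons`, `strand`
#'   (planted round-robin across contigs).
#' @param inside_cds logical vector (recycled over planted rows): which
#'   planted ORFs get a covering decoy CDS.
#' @param seed integer seed.
#' @return list: `genome` (named character vector), `truth` (data.frame
#'   `chrom`, `start`, `end`, `strand`, `start_codon`, 0-based half-open),
#'   `gff` (character vector of GFF3 lines), and writers
#'   `write(dir, prefix)` is left to the caller via [emit_toy_genome()].
#' @export
generate_toy_genome <- function(n_contigs = 1L, contig_len = 3000L,
                                planted = data.frame(
                                  start_codon = "ATG",
                                  codons = 20L, strand = "+"),
                                inside_cds = FALSE, seed = 42L) {
  set.seed(as.integer(seed))
  stopifnot(nrow(planted) >= 0L)
  inside_cds <- rep_len(inside_cds, max(nrow(planted), 1L))
  contigs <- vapply(seq_len(n_contigs), function(i) {
    paste(sample(DNA_BASES, contig_len, replace = TRUE), collapse = "")
  }, character(1L))
  names(contigs) <- paste0("contig", seq_len(n_contigs))
  truth <- list()
  gff <- c("##gff-version 3")
  if (nrow(planted) > 0L) {
    slots_per_contig <- ceiling(nrow(planted) / n_contigs)
    for (r in seq_len(nrow(planted))) {
      ci <- (r - 1L) %% n_contigs + 1L
      slot <- (r - 1L) %/% n_contigs
      len_nt <- 3L * planted$codons[r]
      if ((slot + 1L) * (len_nt + 40L) > contig_len) {
        stop("infeasible packing: planted ORFs exceed contig capacity")
      }
      pos <- slot * (len_nt + 40L) + 21L # 1-based insertion point
      orf <- random_orf(planted$start_codon[r], planted$codons[r])
      ins <- if (planted$strand[r] == "+") orf else revcomp(orf)
      substr(contigs[ci], pos, pos + len_nt - 1L) <- ins
      # shield the flanks so no in-frame stop is accidentally destroyed or
      # an upstream in-frame extension created matters only for truth
      truth[[r]] <- data.frame(
        chrom = names(contigs)[ci], start = pos - 1L,
        end = pos - 1L + len_nt, strand = planted$strand[r],
        start_codon = planted$start_codon[r], stringsAsFactors = FALSE
      )
      if (inside_cds[r]) {
        gff <- c(gff, paste(names(contigs)[ci], "toy", "CDS",
                            pos - 9L, pos + len_nt + 8L, ".",
                            planted$strand[r], "0",
                            paste0("ID=decoy_cds_", r),
                            sep = "\t"))
      }
    }
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(chrom = character(0L), start = integer(0L),
               end = integer(0L), strand = character(0L),
               start_codon = character(0L))
  list(genome = contigs, truth = truth, gff = gff)
}

# ORF with the requested start codon, no internal in-frame stop, stop TAA
random_orf <- function(start_codon, codons) {
  sense <- setdiff(all_kmers(3L), STOP_CODONS)
  paste0(start_codon,
         paste(sample(sense, codons - 2L, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Write toy-genome fixtures to disk
#'
#' @param toy output of [generate_toy_genome()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return named vector of paths (`fasta`, `gff`, `truth_bed`).
#' @export
emit_toy_genome <- function(toy, dir, prefix = "toy") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fa")),
             gff = file.path(dir, paste0(prefix, ".gff3")),
             truth_bed = file.path(dir, paste0(prefix, ".truth.bed")))
  seqs <- Biostrings::DNAStringSet(toy$genome)
  Biostrings::writeXStringSet(seqs, paths[["fasta"]], width = 80L)
  writeLines(toy$gff, paths[["gff"]])
  bed <- data.frame(toy$truth$chrom, toy$truth$start, toy$truth$end,
                    paste0("planted_", seq_len(nrow(toy$truth))),
                    0L, toy$truth$strand)
  write.table(bed, paths[["truth_bed"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths
}
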