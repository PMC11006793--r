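#' Score scanned candidates and apply per-start-codon cutoffs
#'
#' Candidates whose start codon is absent from the cutoff map (AAG and AGG
#' under the defaults) are dropped regardless of score; the rest are encoded
#' with the model's tables/schema, scored, and kept when
#' `score >= cutoffs[start_codon]`.
#'
#' @param candidates a `genome_candidates` data.frame from [scan_smorfs()].
#' @param model a complete `smorf_model`.
#' @param cutoffs named cutoff vector (default the model's own map, else
#'   [default_cutoff_map()]).
#' @return the filtered candidates with the `score` column filled in.
#' @export
score_and_filter <- function(candidates, model, cutoffs = NULL) {
  cutoffs <- cutoffs %||% model$cutoffs %||% default_cutoff_map()
  keep_codon <- candidates$start_codon %in% names(cutoffs)
  candidates <- candidates[keep_codon, , drop = FALSE]
  if (nrow(candidates) == 0L) {
    class(candidates) <- c("genome_candidates", "data.frame")
    return(candidates)
  }
  ds <- orf_dataset(
    id = candidate_ids(candidates),
    upstream3 = candidates$upstream3,
    orf_seq = candidates$orf_seq,
    validate = FALSE
  )
  candidates$score <- predict_scores(model, ds)
  keep <- candidates$score >= unname(cutoffs[candidates$start_codon])
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genome_candidates", "data.frame")
  out
}

candidate_ids <- function(candidates) {
  if (nrow(candidates) == 0L) return(character(0L))
  paste0(candidates$chrom, ":", candidates$start, "-", candidates$end,
         "(", candidates$strand, ")")
}

#' Remove candidates contained in annotated CDS intervals
#'
#' A candidate is removed iff its genomic interval is entirely contained
#' within a single annotated CDS interval on the same strand; partial
#' overlaps and opposite-strand containment are retained. CDS features in
#' common annotations are per exon, so single-interval containment is the
#' operative test.
#'
#' @param candidates a `genome_candidates` data.frame.
#' @param cds a `cds_intervals` data.frame from [read_cds_intervals()].
#' @return the retained candidates.
#' @export
remove_within_cds <- function(candidates, cds) {
  if (nrow(candidates) == 0L || nrow(cds) == 0L) return(candidates)
  contained <- rep(FALSE, nrow(candidates))
  for (grp in split(seq_len(nrow(candidates)),
                    paste(candidates$chrom, candidates$strand))) {
    chrom <- candidates$chrom[grp[1L]]
    strand <- candidates$strand[grp[1L]]
    sel <- cds$chrom == chrom & cds$strand == strand
    if (!any(sel)) next
    q <- IRanges::IRanges(start = candidates$start[grp] + 1L,
                          end = candidates$end[grp])
    s <- IRanges::IRanges(start = cds$start[sel] + 1L, end = cds$end[sel])
    hits <- IRanges::findOverlaps(q, s, type = "within")
    contained[grp[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  out <- candidates[!contained, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genome_candidates", "data.frame")
  out
}

#' Annotate candidates with overlapping gene biotypes
#'
#' Each candidate is assigned the gene name and biotype of any gene feature
#' whose span intersects its interval (any overlap, strand-blind). When
#' several genes overlap, biotype precedence is protein_coding > lncRNA >
#' pseudogene > transcribed_pseudogene > other. Genes lacking a biotype
#' attribute count as `other`; candidates with no overlapping gene keep
#' `overlap_type = "none"`.
#'
#' @param candidates a `genome_candidates` data.frame.
#' @param annotation GFF3/GTF path or an imported `GRanges`.
#' @return candidates with `overlap_gene` and `overlap_type` filled in.
#' @export
annotate_overlap <- function(candidates, annotation) {
  if (nrow(candidates) == 0L) return(candidates)
  gr <- if (methods::is(annotation, "GRanges")) annotation
        else rtracklayer::import(annotation)
  genes <- gr[!is.na(S4Vectors::mcols(gr)$type) &
                as.character(S4Vectors::mcols(gr)$type) == "gene"]
  if (length(genes) == 0L) return(candidates)
  mc <- S4Vectors::mcols(genes)
  biotype <- rep(NA_character_, length(genes))
  for (col in c("gene_biotype", "biotype", "gene_type")) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      biotype[is.na(biotype) & !is.na(v)] <- v[is.na(biotype) & !is.na(v)]
    }
  }
  gname <- rep(NA_character_, length(genes))
  for (col in c("gene_id", "Name", "ID", "gene_name")) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      gname[is.na(gname) & !is.na(v)] <- v[is.na(gname) & !is.na(v)]
    }
  }
  type_class <- classify_biotype(biotype)
  precedence <- c(protein_coding = 1, lncRNA = 2, pseudogene = 3,
                  transcribed_pseudogene = 4, other = 5)
  q <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(candidates$start + 1L, candidates$end)
  )
  hits <- GenomicRanges::findOverlaps(q, genes, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) {
    js <- sh[qh == i]
    j <- js[order(precedence[type_class[js]])[1L]]
    candidates$overlap_gene[i] <- gname[j]
    candidates$overlap_type[i] <- type_class[j]
  }
  candidates
}

classify_biotype <- function(biotype) {
  out <- rep("other", length(biotype))
  out[!is.na(biotype) & biotype == "protein_coding"] <- "protein_coding"
  out[!is.na(biotype) & biotype %in% c("lncRNA", "lincRNA")] <- "lncRNA"
  pseudo <- !is.na(biotype) & grepl("pseudogene", biotype)
  out[pseudo] <- "pseudogene"
  out[pseudo & grepl("transcribed", biotype)] <- "transcribed_pseudogene"
  out
}

#' Write the smORF database files
#'
#' Emits, under `out_prefix`: `.fa` (candidate ORF sequences, ids
#' `chrom:start-end(strand)`), `.bed` (BED6, score = round(1000 * model
#' score)), and `.tsv` (id, upstream3, start_codon, score, overlap_gene,
#' overlap_type). Rows are ordered by (chrom, start, end, strand); empty
#' candidate sets produce valid empty files with the TSV header.
#'
#' @param candidates a `genome_candidates` data.frame.
#' @param out_prefix output path prefix.
#' @return named character vector of the three file paths, invisibly.
#' @export
emit_database <- function(candidates, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  ord <- order(candidates$chrom, candidates$start, candidates$end,
               candidates$strand)
  candidates <- candidates[ord, , drop = FALSE]
  ids <- candidate_ids(candidates)
  paths <- c(fasta = paste0(out_prefix, ".fa"),
             bed = paste0(out_prefix, ".bed"),
             tsv = paste0(out_prefix, ".tsv"))
  seqs <- Biostrings::BStringSet(candidates$orf_seq)
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, paths[["fasta"]], width = 80L)
  bed <- data.frame(
    chrom = candidates$chrom, start = candidates$start,
    end = candidates$end, name = ids,
    score = ifelse(is.na(candidates$score), 0L,
                   as.integer(round(1000 * candidates$score))),
    strand = candidates$strand
  )
  write.table(bed, paths[["bed"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  info <- data.frame(
    id = ids, upstream3 = candidates$upstream3,
    start_codon = candidates$start_codon, score = candidates$score,
    overlap_gene = ifelse(is.na(candidates$overlap_gene), ".",
                          candidates$overlap_gene),
    overlap_type = candidates$overlap_type
  )
  write.table(info, paths[["tsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(paths)
}

#' Translate candidate smORFs to peptide sequences
#'
#' Standard genetic code, trailing stop trimmed. Near-cognate (non-ATG)
#' starts are decoded by the initiator Met-tRNA in vivo, so the first
#' residue is forced to methionine for every start codon.
#'
#' @param candidates a `genome_candidates` data.frame (or any data.frame
#'   with an `orf_seq` column).
#' @return character vector of amino-acid sequences.
#' @export
translate_seps <- function(candidates) {
  orfs <- candidates$orf_seq
  if (length(orfs) == 0L) return(character(0L))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(orfs), no.init.codon = TRUE
  ))
  if (any(grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))) {
    stop("internal stop codon in candidate ORF")
  }
  if (!all(endsWith(aa, "*"))) stop("candidate ORF lacks terminal stop codon")
  aa <- substr(aa, 1L, nchar(aa) - 1L)
  paste0("M", substr(aa, 2L, nchar(aa)))
}

#' Standardized category ratio of SEPs to canonical proteins
#'
#' For a functional category i with `S_i` predicted smORF-encoded peptides
#' and `P_i` canonical proteins, relative to `S_anno` total annotated SEPs
#' and `P_anno` total annotated canonical proteins:
#' `(S_i / P_i) * (P_anno / S_anno)`. A value of 1 means the category holds
#' SEPs and canonical proteins in the global proportion; large values flag
#' SEP-enriched categories.
#'
#' @param S_i,P_i,S_anno,P_anno non-negative counts; `P_i` and `S_anno`
#'   must be positive.
#' @return scalar ratio.
#' @export
standardized_ratio <- function(S_i, P_i, S_anno, P_anno) {
  if (P_i <= 0 || S_anno <= 0) stop("P_i and S_anno must be positive")
  (S_i / P_i) * (P_anno / S_anno)
}
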