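#' @title Six-frame genome scanning for smORF candidates
#' @description
#' The scanner enumerates, on both strands and all three frames of every
#' contig, every span from a configured start codon (ATG plus the
#' near-cognate set CTG, GTG, ACG, TTG, ATT, ATC, ATA, AAG, AGG) to the
#' nearest in-frame stop codon, inclusive, with a codon count inside the
#' configured bounds (default 11-101, stop counted). Nested starts sharing a
#' stop each yield a candidate unless `longest_only` is set. Coordinates are
#' always reported on the forward strand, 0-based half-open; the upstream
#' context is read strand-aware from the 3 preceding genomic bases,
#' `N`-padded at contig edges. Codons containing `N` are never starts or
#' stops and candidates containing `N` anywhere in the ORF are discarded.
#' @name genomescan
NULL

SCAN_START_CODONS <- c("ATG", "CTG", "GTG", "ACG", "TTG",
                       "ATT", "ATC", "ATA", "AAG", "AGG")

#' Default per-start-codon score cutoffs
#'
#' Precision-targeted thresholds by start-codon efficiency rank: 0.780 for
#' ATG and CTG (precision target 0.95), 0.968 for GTG and ACG (target 0.99),
#' 1.000 for TTG/ATT/ATC/ATA; AAG and AGG are absent from the map, which
#' excludes them from any filtered output regardless of score.
#'
#' @return named numeric vector start_codon -> cutoff.
#' @export
default_cutoff_map <- function() {
  c(ATG = 0.780, CTG = 0.780, GTG = 0.968, ACG = 0.968,
    TTG = 1.000, ATT = 1.000, ATC = 1.000, ATA = 1.000)
}

#' Scan a genome for smORF candidates
#'
#' @param genome a FASTA path, a `Biostrings::DNAStringSet`, or a named
#'   character vector of contig sequences.
#' @param start_codons start codons to accept (default the full ATG +
#'   near-cognate set, including AAG/AGG, which downstream filtering drops).
#' @param min_codons,max_codons ORF length bounds in codons, stop included.
#' @param longest_only if `TRUE`, keep only the 5'-most start per
#'   (stop, frame, strand).
#' @return a `genome_candidates` data.frame: `chrom`, `start`, `end`
#'   (forward-strand, 0-based half-open), `strand`, `frame` (0-2 on its own
#'   strand), `start_codon`, `upstream3`, `orf_seq`, `score` (NA until
#'   scored), `overlap_gene`, `overlap_type`.
#' @export
scan_smorfs <- function(genome, start_codons = SCAN_START_CODONS,
                        min_codons = 11L, max_codons = 101L,
                        longest_only = FALSE) {
  stopifnot(min_codons >= 2L, min_codons <= max_codons)
  contigs <- as_contig_strings(genome)
  out <- lapply(names(contigs), function(chrom) {
    scan_contig(chrom, contigs[[chrom]], start_codons,
                min_codons, max_codons, longest_only)
  })
  res <- do.call(rbind, c(out, list(empty_candidates())))
  res <- res[order(res$chrom, res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("genome_candidates", "data.frame")
  res
}

as_contig_strings <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(toupper(out))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("contig", seq_along(genome))
    }
    return(toupper(genome))
  }
  stop("genome must be a FASTA path, DNAStringSet or named character vector")
}

empty_candidates <- function() {
  data.frame(chrom = character(0L), start = integer(0L), end = integer(0L),
             strand = character(0L), frame = integer(0L),
             start_codon = character(0L), upstream3 = character(0L),
             orf_seq = character(0L), score = numeric(0L),
             overlap_gene = character(0L), overlap_type = character(0L),
             stringsAsFactors = FALSE)
}

scan_contig <- function(chrom, fwd, start_codons,
                        min_codons, max_codons, longest_only) {
  L <- nchar(fwd)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") fwd else revcomp(fwd)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3L
      if (n_codons < min_codons) next
      starts_nt <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
      codons <- substring(s, starts_nt, starts_nt + 2L)
      stop_idx <- which(codons %in% STOP_CODONS)
      start_idx <- which(codons %in% start_codons)
      if (length(stop_idx) == 0L || length(start_idx) == 0L) next
      # nearest in-frame stop strictly after each start
      nxt <- findInterval(start_idx, stop_idx) + 1L
      has_stop <- nxt <= length(stop_idx)
      start_idx <- start_idx[has_stop]
      stop_for <- stop_idx[nxt[has_stop]]
      len_codons <- stop_for - start_idx + 1L
      keep <- len_codons >= min_codons & len_codons <= max_codons
      start_idx <- start_idx[keep]
      stop_for <- stop_for[keep]
      if (length(start_idx) == 0L) next
      if (longest_only) {
        first <- !duplicated(stop_for) # start_idx ascending per stop
        start_idx <- start_idx[first]
        stop_for <- stop_for[first]
      }
      a <- starts_nt[start_idx]              # 1-based on strand s
      b <- starts_nt[stop_for] + 2L
      orf <- substring(s, a, b)
      ok <- !grepl("N", orf, fixed = TRUE)
      if (!any(ok)) next
      a <- a[ok]; b <- b[ok]; orf <- orf[ok]
      up <- vapply(a, function(p) {
        if (p >= 4L) substr(s, p - 3L, p - 1L)
        else paste0(strrep("N", 4L - p),
                    if (p > 1L) substr(s, 1L, p - 1L) else "")
      }, character(1L))
      if (strand == "+") {
        g_start <- a - 1L
        g_end <- b
      } else {
        g_start <- L - b
        g_end <- L - a + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = g_start, end = g_end, strand = strand,
        frame = frame, start_codon = substr(orf, 1L, 3L),
        upstream3 = up, orf_seq = orf, score = NA_real_,
        overlap_gene = NA_character_, overlap_type = "none",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(empty_candidates())))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
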