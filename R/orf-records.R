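#' @title ORF record datasets
#' @description
#' The package's central container is the "ORF dataset": a plain
#' `data.frame` (class `orf_dataset`) with one row per ORF and columns
#' `id`, `upstream3`, `orf_seq`, `start_codon`, `label`, `source`.
#' `upstream3` is the 3-nt genomic/transcript context immediately 5' of the
#' start codon (sites -3, -2, -1), `N`-padded where the context runs off the
#' end of the molecule. `orf_seq` runs from the start codon through the stop
#' codon inclusive.
#'
#' Validity of a record (enforced by [validate_orf_records()]):
#' * `nchar(orf_seq)` is a multiple of 3 and 2..101 codons (stop included);
#' * `orf_seq` starts with `start_codon` and ends with TAA/TAG/TGA;
#' * no internal in-frame stop codon;
#' * `nchar(upstream3) == 3`, alphabet `A/C/G/T/N`.
#' @name orf_dataset
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
MAX_SMORF_CODONS <- 101L

#' Construct an ORF dataset
#'
#' @param id character vector of unique record identifiers.
#' @param upstream3 3-letter upstream contexts (sites -3..-1), `N` allowed.
#' @param orf_seq ORF nucleotide sequences, start through stop codon.
#' @param label one of `"positive"`, `"negative"`, `"unknown"` (recycled).
#' @param source free-text provenance tag (recycled).
#' @param split_tag `"train"`, `"test"` or `"unsplit"`.
#' @param validate if `TRUE` (default) reject records violating the ORF
#'   invariants with an error; use [validate_orf_records()] to inspect first.
#' @return an `orf_dataset` data.frame.
#' @export
orf_dataset <- function(id, upstream3, orf_seq,
                        label = "unknown", source = "",
                        split_tag = "unsplit", validate = TRUE) {
  df <- data.frame(
    id = as.character(id),
    upstream3 = toupper(as.character(upstream3)),
    orf_seq = toupper(as.character(orf_seq)),
    start_codon = toupper(substr(as.character(orf_seq), 1L, 3L)),
    label = rep_len(as.character(label), length(id)),
    source = rep_len(as.character(source), length(id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$id)) stop("record ids must be unique")
  if (!all(df$label %in% c("positive", "negative", "unknown"))) {
    stop("label must be 'positive', 'negative' or 'unknown'")
  }
  if (validate && nrow(df) > 0L) {
    ok <- validate_orf_records(df)
    if (!all(ok)) {
      stop(sum(!ok), " record(s) violate ORF invariants (first: ",
           df$id[which(!ok)[1L]], ")")
    }
  }
  attr(df, "split_tag") <- match.arg(split_tag, c("unsplit", "train", "test"))
  class(df) <- c("orf_dataset", "data.frame")
  df
}

#' Check ORF record invariants
#'
#' @param df a data.frame with at least `upstream3` and `orf_seq` columns.
#' @param max_codons maximum ORF length in codons, stop codon counted.
#' @return logical vector, `TRUE` where the record is a valid smORF record.
#' @export
validate_orf_records <- function(df, max_codons = MAX_SMORF_CODONS) {
  n <- nchar(df$orf_seq)
  ok_len <- n %% 3L == 0L & n >= 6L & n <= 3L * max_codons
  ok_up <- nchar(df$upstream3) == 3L &
    !grepl("[^ACGTN]", df$upstream3)
  ok_alpha <- !grepl("[^ACGTN]", df$orf_seq)
  ok_stop <- substr(df$orf_seq, pmax(n - 2L, 1L), n) %in% STOP_CODONS
  ok_internal <- !vapply(seq_along(n), function(i) {
    if (!ok_len[i] || !ok_alpha[i]) return(TRUE)
    cods <- codon_split(df$orf_seq[i])
    any(cods[-length(cods)] %in% STOP_CODONS)
  }, logical(1L))
  ok_len & ok_up & ok_alpha & ok_stop & ok_internal
}

#' Split a nucleotide string into in-frame codons
#' @param seq a nucleotide string with length divisible by 3.
#' @return character vector of codons.
#' @export
codon_split <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0L))
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Read ORF records from FASTA
#'
#' Each FASTA entry is expected to be the 3 upstream nucleotides followed by
#' the ORF (start codon through stop codon). Entries violating the ORF record
#' invariants are skipped with a message reporting the count.
#'
#' @param path FASTA file path.
#' @param label label assigned to all parsed records.
#' @param max_codons maximum ORF length in codons (stop included).
#' @return an `orf_dataset`; attribute `n_skipped` records the skip count.
#' @export
read_orf_fasta <- function(path, label = "unknown",
                           max_codons = MAX_SMORF_CODONS) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  txt <- toupper(as.character(seqs))
  ids <- sub("\\s.*$", "", names(seqs))
  keep_shape <- nchar(txt) >= 9L & (nchar(txt) - 3L) %% 3L == 0L
  df <- data.frame(
    id = ids,
    upstream3 = substr(txt, 1L, 3L),
    orf_seq = substr(txt, 4L, nchar(txt)),
    stringsAsFactors = FALSE
  )
  ok <- keep_shape
  ok[keep_shape] <- validate_orf_records(df[keep_shape, , drop = FALSE],
                                         max_codons = max_codons)
  n_skip <- sum(!ok)
  if (n_skip > 0L) {
    message("read_orf_fasta: skipped ", n_skip,
            " entr", if (n_skip == 1L) "y" else "ies",
            " violating ORF invariants")
  }
  if (!any(ok)) stop("no valid ORF records in ", path)
  out <- orf_dataset(
    id = df$id[ok], upstream3 = df$upstream3[ok], orf_seq = df$orf_seq[ok],
    label = label, source = basename(path), validate = FALSE
  )
  attr(out, "n_skipped") <- n_skip
  out
}

#' Write ORF records to FASTA
#'
#' Inverse of [read_orf_fasta()]: each entry is `upstream3` concatenated with
#' `orf_seq`, so a read/write round trip preserves sequence content exactly.
#'
#' @param dataset an `orf_dataset`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(dataset, path) {
  seqs <- Biostrings::BStringSet(paste0(dataset$upstream3, dataset$orf_seq))
  names(seqs) <- dataset$id
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Extract the maximal ATG-initiated ORF from a transcript
#'
#' Scans the three forward frames of a sense-orientation transcript for
#' ATG-initiated, stop-terminated ORFs and returns the longest one (ties go to
#' the 5'-most start). The upstream context is the 3 nt preceding the ATG,
#' `N`-padded when the ORF starts within the first three bases. Used to derive
#' negative training examples from non-coding transcripts.
#'
#' @param transcript nucleotide string (sense strand).
#' @param id identifier for the returned record.
#' @param max_codons if non-`NULL`, ORFs longer than this (codons, stop
#'   included) are ignored.
#' @return a one-row `orf_dataset`, or `NULL` if no ORF exists.
#' @export
extract_max_orf <- function(transcript, id = "orf1", max_codons = NULL) {
  transcript <- toupper(transcript)
  n <- nchar(transcript)
  best <- NULL
  starts <- as.integer(gregexpr("ATG", transcript)[[1L]])
  if (length(starts) == 1L && starts[1L] == -1L) return(NULL)
  for (s in sort(starts)) {
    # nearest in-frame stop at or after the start
    p <- s + 3L
    stop_at <- NA_integer_
    while (p + 2L <= n) {
      if (substr(transcript, p, p + 2L) %in% STOP_CODONS) {
        stop_at <- p
        break
      }
      p <- p + 3L
    }
    if (is.na(stop_at)) next
    len <- stop_at + 2L - s + 1L
    if (!is.null(max_codons) && len / 3L > max_codons) next
    if (is.null(best) || len > best$len) {
      best <- list(start = s, len = len)
    }
  }
  if (is.null(best)) return(NULL)
  orf <- substr(transcript, best$start, best$start + best$len - 1L)
  up_start <- best$start - 3L
  if (up_start >= 1L) {
    up <- substr(transcript, up_start, best$start - 1L)
  } else {
    avail <- best$start - 1L
    up <- paste0(strrep("N", 3L - avail),
                 if (avail > 0L) substr(transcript, 1L, avail) else "")
  }
  orf_dataset(id = id, upstream3 = up, orf_seq = orf, validate = FALSE)
}

#' Read CDS intervals from a GFF3/GTF annotation
#'
#' Collects all features of type `CDS`, converting the 1-based closed
#' GFF/GTF coordinates to the package's internal 0-based half-open
#' convention. Used to drop genome-scan candidates that sit inside canonical
#' coding sequence.
#'
#' @param path GFF3 or GTF file (dialect auto-detected by extension, both
#'   parsed by `rtracklayer`).
#' @return a `cds_intervals` data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`; empty with a warning when the
#'   annotation contains no CDS features.
#' @export
read_cds_intervals <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  gr <- rtracklayer::import(path)
  cds <- gr[!is.na(S4Vectors::mcols(gr)$type) &
              as.character(S4Vectors::mcols(gr)$type) == "CDS"]
  if (length(cds) == 0L) {
    warning("no CDS features found in ", path)
    out <- data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), strand = character(0L),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(cds)),
      start = GenomicRanges::start(cds) - 1L,
      end = GenomicRanges::end(cds),
      strand = as.character(GenomicRanges::strand(cds)),
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("cds_intervals", "data.frame")
  out
}
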