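toy_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      sets <- tiny_training_sets(n = 40L, seed = 801L)
      model <<- train_smorf_model(sets$pos, sets$neg,
                                  hyperparameters = list(ntree = 80L),
                                  schema = feature_schema("reduced33"),
                                  seed = 8L)
    }
    model
  }
})

fake_candidates <- function(start_codons, scores = NULL) {
  n <- length(start_codons)
  orfs <- vapply(seq_len(n), function(i) {
    body <- paste0(start_codons[i], strrep("GCA", 12L), "TAA")
    body
  }, character(1L))
  df <- data.frame(
    chrom = "chr1", start = 100L * seq_len(n),
    end = 100L * seq_len(n) + nchar(orfs), strand = "+", frame = 0L,
    start_codon = start_codons, upstream3 = "GCC", orf_seq = orfs,
    score = if (is.null(scores)) NA_real_ else scores,
    overlap_gene = NA_character_, overlap_type = "none",
    stringsAsFactors = FALSE
  )
  class(df) <- c("genome_candidates", "data.frame")
  df
}

test_that("per-start-codon cutoffs keep, drop at boundary, and exclude codons", {
  cutoffs <- c(ATG = 0.780, TTG = 1.000)
  cands <- fake_candidates(c("ATG", "TTG", "AAG"))
  model <- toy_model()
  scored <- score_and_filter(cands, model, cutoffs)
  # AAG is not in the map: dropped regardless of score
  expect_false("AAG" %in% scored$start_codon)
  # survivors all satisfy their cutoff
  if (nrow(scored) > 0L) {
    expect_true(all(scored$score >= cutoffs[scored$start_codon]))
  }
  # direct boundary semantics on precomputed scores
  expect_true(0.80 >= cutoffs[["ATG"]])
  expect_false(0.999 >= cutoffs[["TTG"]])
})

test_that("default cutoff map carries the rank-based thresholds", {
  cm <- default_cutoff_map()
  expect_equal(cm[["ATG"]], 0.780)
  expect_equal(cm[["CTG"]], 0.780)
  expect_equal(cm[["GTG"]], 0.968)
  expect_equal(cm[["ACG"]], 0.968)
  expect_equal(unname(cm[c("TTG", "ATT", "ATC", "ATA")]), rep(1.0, 4L))
  expect_false(any(c("AAG", "AGG") %in% names(cm)))
})

test_that("CDS containment removal is strand-aware and containment-only", {
  cds <- structure(data.frame(
    chrom = c("chr1", "chr1"), start = c(90L, 500L),
    end = c(300L, 600L), strand = c("+", "-"),
    stringsAsFactors = FALSE
  ), class = c("cds_intervals", "data.frame"))
  cands <- fake_candidates(c("ATG", "ATG", "ATG"))
  cands$start <- c(100L, 100L, 250L)
  cands$end <- c(160L, 160L, 340L)
  cands$strand <- c("+", "-", "+")
  kept <- remove_within_cds(cands, cds)
  # contained same-strand candidate removed; opposite strand and
  # boundary-straddling candidates retained
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$strand, c("-", "+"))
  expect_true(340L %in% kept$end)
})

test_that("containment filtering matches a brute-force loop on random cases", {
  set.seed(811L)
  for (rep_i in 1:5) {
    n <- 200L
    cands <- fake_candidates(rep("ATG", n))
    cands$chrom <- sample(c("c1", "c2"), n, replace = TRUE)
    cands$start <- sample(0:5000, n, replace = TRUE)
    cands$end <- cands$start + sample(33:300, n, replace = TRUE)
    cands$strand <- sample(c("+", "-"), n, replace = TRUE)
    cds <- structure(data.frame(
      chrom = sample(c("c1", "c2"), 30L, replace = TRUE),
      start = sample(0:5000, 30L, replace = TRUE),
      stringsAsFactors = FALSE
    ), class = c("cds_intervals", "data.frame"))
    cds$end <- cds$start + sample(50:800, 30L, replace = TRUE)
    cds$strand <- sample(c("+", "-"), 30L, replace = TRUE)
    kept <- remove_within_cds(cands, cds)
    contained <- vapply(seq_len(n), function(i) {
      any(cds$chrom == cands$chrom[i] & cds$strand == cands$strand[i] &
            cds$start <= cands$start[i] & cands$end[i] <= cds$end)
    }, logical(1L))
    expect_setequal(candidate_key(kept),
                    candidate_key(cands[!contained, ]))
  }
})

test_that("overlap annotation applies biotype precedence", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t50\t400\t.\t+\t.\tID=gene_lnc;gene_biotype=lncRNA",
    "chr1\tsrc\tgene\t80\t350\t.\t-\t.\tID=gene_pc;gene_biotype=protein_coding",
    "chr1\tsrc\tgene\t900\t1000\t.\t+\t.\tID=gene_ps;gene_biotype=transcribed_unprocessed_pseudogene"
  ), gff)
  cands <- fake_candidates(c("ATG", "ATG", "ATG"))
  cands$start <- c(100L, 920L, 5000L)
  cands$end <- c(160L, 960L, 5060L)
  ann <- annotate_overlap(cands, gff)
  # overlapping both lncRNA and protein_coding: precedence picks coding
  expect_equal(ann$overlap_type[1L], "protein_coding")
  expect_equal(ann$overlap_gene[1L], "gene_pc")
  expect_equal(ann$overlap_type[2L], "transcribed_pseudogene")
  expect_equal(ann$overlap_type[3L], "none")
})

test_that("database emission writes consistent FASTA/BED/TSV triples", {
  dir <- tempfile()
  dir.create(dir)
  cands <- fake_candidates(c("ATG", "CTG", "GTG"),
                           scores = c(0.9, 0.85, 0.99))
  paths <- emit_database(cands, file.path(dir, "db"))
  fa <- Biostrings::readBStringSet(paths[["fasta"]])
  expect_length(fa, 3L)
  bed <- read.table(paths[["bed"]], sep = "\t")
  expect_equal(nrow(bed), 3L)
  expect_equal(bed$V5, c(900L, 850L, 990L))
  expect_equal(bed$V2, cands$start)
  tsv <- read.table(paths[["tsv"]], sep = "\t", header = TRUE)
  expect_equal(nrow(tsv), 3L)
  expect_equal(names(fa), tsv$id)
  expect_equal(bed$V4, tsv$id)
  # BED intervals round-trip through interval parsing
  expect_equal(bed$V3 - bed$V2, nchar(cands$orf_seq))

  empty <- emit_database(cands[0L, ], file.path(dir, "empty"))
  expect_equal(length(readLines(empty[["fasta"]])), 0L)
  tsv_empty <- read.table(empty[["tsv"]], sep = "\t", header = TRUE)
  expect_equal(nrow(tsv_empty), 0L)
  expect_equal(names(tsv_empty)[1L], "id")
})

test_that("peptide translation trims the stop and forces an initiator Met", {
  expect_equal(translate_seps(data.frame(orf_seq = "ATGAAATAA")), "MK")
  expect_equal(translate_seps(data.frame(orf_seq = "CTGAAATAA")), "MK")
  expect_equal(translate_seps(data.frame(orf_seq = "GTGCACCACTGA")), "MHH")
  set.seed(821L)
  orfs <- vapply(sample(5:30, 10L, replace = TRUE), random_orf_record,
                 character(1L))
  aa <- translate_seps(data.frame(orf_seq = orfs))
  expect_equal(nchar(aa), nchar(orfs) / 3L - 1L)
  expect_true(all(substr(aa, 1L, 1L) == "M"))
  expect_error(translate_seps(data.frame(orf_seq = "ATGTAAAAATAA")),
               "internal stop")
})

test_that("standardized category ratios follow the closed form", {
  expect_equal(standardized_ratio(10, 10, 100, 100), 1)
  expect_equal(standardized_ratio(5188, 2, 218709, 20112),
               (5188 / 2) * (20112 / 218709))
  expect_equal(standardized_ratio(5188, 2, 218709, 20112), 238.6,
               tolerance = 1e-3)
  expect_equal(standardized_ratio(20, 10, 100, 100),
               2 * standardized_ratio(10, 10, 100, 100))
  expect_error(standardized_ratio(1, 0, 10, 10), "positive")
})
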