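# tables with controlled ratios for hand-checkable log-ratio features
flat_tables <- function() {
  sets <- tiny_training_sets(n = 10L, seed = 21L)
  tb <- fit_feature_tables(sets$pos, sets$pos)  # pos == neg everywhere
  tb
}

test_that("nucleotide bias is zero under identical tables and ln-ratio otherwise", {
  tb <- flat_tables()
  v <- nucleotide_bias("ACG", "ATGAAATAA", tb)
  expect_equal(unname(v), rep(0, 6L))
  expect_length(v, 6L)

  tb$site_prob_pos["A", "-3"] <- 0.5
  tb$site_prob_neg["A", "-3"] <- 0.25
  v2 <- nucleotide_bias("ACG", "ATGAAATAA", tb)
  expect_equal(unname(v2[1L]), log(2))

  # N at a TIS site contributes exactly 0
  v3 <- nucleotide_bias("NNN", "ATGAAATAA", tb)
  expect_equal(unname(v3[1:3]), rep(0, 3L))
})

test_that("codon bias is the mean log usage ratio over all codons", {
  tb <- flat_tables()
  expect_equal(codon_bias("ATGAAATAA", tb), 0)

  # per-codon ratios 2, 1, 0.5 average to zero on the log scale
  tb$codon_usage_pos[c("ATG", "TAA")] <- c(0.5, 0.2)
  tb$codon_usage_neg[c("ATG", "TAA")] <- c(0.25, 0.4)
  r_aaa <- tb$codon_usage_pos[["AAA"]] / tb$codon_usage_neg[["AAA"]]
  expect_equal(r_aaa, 1)
  expect_equal(codon_bias("ATGAAATAA", tb),
               (log(2) + log(1) + log(0.5)) / 3)
})

test_that("codon bias is a mean: invariant to repeating the codon content", {
  sets <- tiny_training_sets(n = 15L, seed = 31L)
  tb <- fit_feature_tables(sets$pos, sets$neg)
  one <- codon_bias("ATGCCCTAA", tb)
  # same multiset of codon log-ratios, three times over
  rep3 <- codon_bias("ATGCCCTAAATGCCCTAAATGCCCTAA", tb)
  expect_equal(rep3, one)
})

test_that("hexamer score sums in-frame log ratios and grows with length", {
  tb <- flat_tables()
  expect_equal(hexamer_score("ATGAAATAA", tb), 0)

  tb$hexamer_freq_pos[c("ATGAAA", "AAATAA")] <- c(2e-4, 3e-4)
  tb$hexamer_freq_neg[c("ATGAAA", "AAATAA")] <- c(1e-4, 1e-4)
  expect_equal(hexamer_score("ATGAAATAA", tb), log(2) + log(3))

  # appending codons adds exactly the new hexamers' ratios
  tb$hexamer_freq_pos["AAAAAA"] <- 5e-4
  tb$hexamer_freq_neg["AAAAAA"] <- 1e-4
  base <- hexamer_score("ATGAAATAA", tb)
  # ATG AAA AAA TAA: hexamers ATGAAA, AAAAAA, AAATAA
  expect_equal(hexamer_score("ATGAAAAAATAA", tb), base + log(5))
  expect_warning(hexamer_score("ATG", tb), "hexamer")
})

test_that("Fickett position parameters match hand counts and codon permutation", {
  v <- fickett_scores("AAAAAAAAA")
  expect_equal(unname(v[c("fickett_A", "fickett_T")]), c(3 / 4, 0))
  expect_equal(names(v), paste0("fickett_", c("T", "A", "C", "G")))

  # equal per-position counts k give k/(k+1) for every base
  v2 <- fickett_scores("ACGTACGTACGT")  # each base once per position
  expect_equal(unname(v2), rep(1 / 2, 4L))

  set.seed(17L)
  orf <- random_orf_record(20L)
  cods <- substring(orf, seq(1L, nchar(orf) - 2L, 3L),
                    seq(3L, nchar(orf), 3L))
  perm <- paste(sample(cods), collapse = "")
  expect_equal(fickett_scores(perm), fickett_scores(orf))
})

test_that("k-mer frequencies are correct, ordered, and normalized", {
  expect_equal(unname(kmer_freq("AAAA", 1L)), c(1, 0, 0, 0))
  v <- kmer_freq("ATGTAA", 2L)
  expect_equal(v[["mer2_AT"]], 1 / 5)
  expect_equal(v[["mer2_TG"]], 1 / 5)
  expect_equal(v[["mer2_AA"]], 1 / 5)
  expect_equal(sum(v), 1)
  set.seed(23L)
  for (k in 1:4) {
    orf <- random_orf_record(30L)
    expect_equal(sum(kmer_freq(orf, k)), 1, tolerance = 1e-9)
  }
  # windows containing N are skipped
  vn <- kmer_freq("ANAT", 2L)
  expect_equal(vn[["mer2_AT"]], 1)
})

test_that("gapped pair frequencies match hand enumeration", {
  v <- gap_freq("AAAAA", 1L, "gap")
  expect_equal(v[["gap1_A.A"]], 1)
  v2 <- gap_freq("ATGCA", 1L, "gap")
  expect_equal(v2[["gap1_A.G"]], 1 / 3)
  expect_equal(v2[["gap1_T.C"]], 1 / 3)
  expect_equal(v2[["gap1_G.A"]], 1 / 3)
  # bigap: dinucleotide pairs with a gap
  v3 <- gap_freq("AATTAA", 2L, "bigap")
  expect_equal(v3[["bigap2_AA.AA"]], 1)
  # shorter than the span: all-zero
  expect_equal(sum(gap_freq("AAA", 3L, "bigap")), 0)
})

test_that("schema layouts have the documented dimensions", {
  expect_equal(schema_dim(feature_schema("complete")), 1169L)
  expect_equal(schema_dim(feature_schema("reduced33")), 33L)
  expect_equal(schema_dim(feature_schema("final32")), 32L)
  # the dropped lowest-ranked feature is the TT dinucleotide frequency
  expect_false("mer2_TT" %in% feature_schema("final32")$feature_names)
  expect_true("mer2_TT" %in% feature_schema("reduced33")$feature_names)
  expect_equal(feature_schema("final32")$feature_names[1:2],
               c("orf_length", "nb_-3"))
})

test_that("encoding is deterministic and consistent across schemas", {
  sets <- tiny_training_sets(n = 15L, seed = 41L)
  tb <- fit_feature_tables(sets$pos, sets$neg)
  rec <- sets$pos[1L, ]
  for (sch in c("complete", "reduced33", "final32")) {
    s <- feature_schema(sch)
    v1 <- encode_record(rec$upstream3, rec$orf_seq, tb, s)
    v2 <- encode_record(rec$upstream3, rec$orf_seq, tb, s)
    expect_identical(v1, v2)
    expect_length(v1, schema_dim(s))
    expect_equal(names(v1), s$feature_names)
  }
  # final32 features agree with the same features in reduced33
  r33 <- encode_record(rec$upstream3, rec$orf_seq, tb,
                       feature_schema("reduced33"))
  f32 <- encode_record(rec$upstream3, rec$orf_seq, tb,
                       feature_schema("final32"))
  expect_equal(f32, r33[names(f32)])
  expect_error(feature_schema_from_features("not_a_feature"), "unknown")
})

test_that("log-ratio features negate when the class tables are swapped", {
  sets <- tiny_training_sets(n = 20L, seed = 51L)
  tb <- fit_feature_tables(sets$pos, sets$neg)
  swapped <- tb
  swapped$site_prob_pos <- tb$site_prob_neg
  swapped$site_prob_neg <- tb$site_prob_pos
  swapped$codon_usage_pos <- tb$codon_usage_neg
  swapped$codon_usage_neg <- tb$codon_usage_pos
  swapped$hexamer_freq_pos <- tb$hexamer_freq_neg
  swapped$hexamer_freq_neg <- tb$hexamer_freq_pos
  rec <- sets$neg[3L, ]
  expect_equal(nucleotide_bias(rec$upstream3, rec$orf_seq, swapped),
               -nucleotide_bias(rec$upstream3, rec$orf_seq, tb))
  expect_equal(codon_bias(rec$orf_seq, swapped),
               -codon_bias(rec$orf_seq, tb))
  expect_equal(hexamer_score(rec$orf_seq, swapped),
               -hexamer_score(rec$orf_seq, tb))
})

test_that("planted TIS bias separates class means of the bias features", {
  sets <- tiny_training_sets(n = 60L, strength = 1, seed = 61L)
  tb <- fit_feature_tables(sets$pos, sets$neg)
  nb_pos <- colMeans(encode_dataset(sets$pos, tb,
                                    feature_schema("reduced33"))[,
                     c("nb_-3", "nb_4")])
  nb_neg <- colMeans(encode_dataset(sets$neg, tb,
                                    feature_schema("reduced33"))[,
                     c("nb_-3", "nb_4")])
  expect_true(all(nb_pos > nb_neg))
  cb_pos <- mean(vapply(sets$pos$orf_seq, codon_bias, numeric(1L),
                        tables = tb))
  cb_neg <- mean(vapply(sets$neg$orf_seq, codon_bias, numeric(1L),
                        tables = tb))
  expect_gt(cb_pos, cb_neg)
})
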