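# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# six-frame ORF enumeration by walking codon vectors
oracle_scan <- function(contigs, start_codons, min_codons, max_codons,
                        longest_only = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (chrom in names(contigs)) {
    fwd <- contigs[[chrom]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else oracle_revcomp(fwd)
      for (fr in 0:2) {
        nc <- (L - fr) %/% 3L
        if (nc < 1L) next
        pos1 <- fr + 3L * (seq_len(nc) - 1L) + 1L
        cods <- substring(s, pos1, pos1 + 2L)
        taken_stop <- character(0L)
        for (i in seq_len(nc)) {
          if (!(cods[i] %in% start_codons)) next
          found <- NA_integer_
          j <- i + 1L
          while (j <= nc) {
            if (cods[j] %in% stops) {
              found <- j
              break
            }
            j <- j + 1L
          }
          if (is.na(found)) next
          lenc <- found - i + 1L
          if (lenc < min_codons || lenc > max_codons) next
          if (longest_only) {
            key <- as.character(found)
            if (key %in% taken_stop) next
            taken_stop <- c(taken_stop, key)
          }
          a <- pos1[i]
          b <- pos1[found] + 2L
          orf <- substr(s, a, b)
          if (grepl("N", orf, fixed = TRUE)) next
          if (strand == "+") {
            gs <- a - 1L
            ge <- b
          } else {
            gs <- L - b
            ge <- L - a + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = gs, end = ge, strand = strand,
            orf_seq = orf, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), strand = character(0L),
                      orf_seq = character(0L)))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
}

candidate_key <- function(df) {
  paste(df$chrom, df$start, df$end, df$strand, df$orf_seq)
}

# longest ATG..stop span over the three forward frames (ties: 5'-most)
oracle_max_orf <- function(transcript) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(transcript)
  best <- NULL
  for (a in seq_len(max(n - 5L, 0L))) {
    if (substr(transcript, a, a + 2L) != "ATG") next
    p <- a + 3L
    while (p + 2L <= n) {
      if (substr(transcript, p, p + 2L) %in% stops) {
        len <- p + 2L - a + 1L
        if (is.null(best) || len > best$len) best <- list(start = a, len = len)
        break
      }
      p <- p + 3L
    }
  }
  best
}

# probability-of-correct-ranking AUC (Mann-Whitney pair counting)
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# direct metric formulas, written out independently
oracle_metrics <- function(tp, tn, fp, fn) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe(tp, tp + fn)
  sp <- safe(tn, tn + fp)
  pre <- safe(tp, tp + fp)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- safe(2 * pre * sn, pre + sn)
  hm <- safe(2 * sp * sn, sp + sn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(SN = sn, SP = sp, PRE = pre, ACC = acc, F1S = f1, HM = hm, MCC = mcc)
}

# naive MIQ ranking over a small feature matrix (own discretization + MI)
oracle_mrmr <- function(X, y) {
  disc <- function(v) {
    m <- mean(v)
    s <- sd(v)
    if (s == 0) return(rep(1L, length(v)))
    ifelse(v < m - s, 1L, ifelse(v < m + s, 2L, 3L))
  }
  mi <- function(a, b) {
    out <- 0
    for (va in unique(a)) {
      for (vb in unique(b)) {
        pab <- mean(a == va & b == vb)
        if (pab == 0) next
        out <- out + pab * log(pab / (mean(a == va) * mean(b == vb)))
      }
    }
    out
  }
  D <- apply(X, 2L, disc)
  yv <- as.integer(y)
  feats <- colnames(X)
  N <- length(yv)
  # relevance screened by the G-test: 2N * MI ~ chi-square under
  # independence; non-significant features carry zero relevance
  rel <- sapply(feats, function(f) {
    m <- mi(D[, f], yv)
    df <- (length(unique(D[, f])) - 1L) * (length(unique(yv)) - 1L)
    if (df < 1L || 2 * N * m <= qchisq(0.999, df)) 0 else m
  })
  sel <- character(0L)
  cand <- feats
  while (length(cand) > 0L) {
    if (length(sel) == 0L) {
      sc <- rel[cand]
    } else {
      sc <- sapply(cand, function(f) {
        if (rel[f] == 0) return(0)
        red <- mean(sapply(sel, function(s) mi(D[, f], D[, s])))
        if (red <= 0) Inf else rel[f] / red
      })
    }
    pick <- cand[order(-sc, cand)[1L]]
    sel <- c(sel, pick)
    cand <- setdiff(cand, pick)
  }
  sel
}

# small labelled synthetic sets shared across tests (cheap, fixed seed)
tiny_training_sets <- function(n = 40L, strength = 1, seed = 101L) {
  generate_training_sets(synth_config(
    n_pos = n, n_neg = n,
    codon_bias_strength = strength, tis_bias_strength = strength,
    length_range = c(11L, 60L), seed = seed
  ))
}

random_orf_record <- function(codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1L, function(r)
                        paste0(r[1], r[2], r[3])),
    c("TAA", "TAG", "TGA")
  )
  paste0("ATG", paste(sample(sense, codons - 2L, replace = TRUE),
                      collapse = ""), sample(c("TAA", "TAG", "TGA"), 1L))
}
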