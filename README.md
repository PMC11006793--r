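# smorfcp

Coding-potential modelling and genome scanning for small open reading
frames (smORFs).

## What it is for

smORFs — ORFs of at most 101 codons including the stop — encode
microproteins that conventional annotation pipelines largely miss. This
package is for researchers who want to (a) train a species-specific
classifier that separates coding smORFs from the ORFs that occur by chance
in non-coding RNA, and (b) apply it in a six-frame scan of a genome to
build a database of candidate smORFs, including ones initiated at
near-cognate (non-ATG) start codons such as CTG and GTG.

Training inputs are two FASTA sets of ORFs, each sequence prefixed with its
three upstream nucleotides: positives are mRNA CDSs (≤ 101 codons),
negatives are maximal ATG-initiated ORFs extracted from non-coding
transcripts. A synthetic-data module generates both, plus toy genomes with
planted smORFs, so the whole pipeline runs and is tested without any
downloads.

## The model

Each ORF record is encoded into a feature vector combining:

* **TIS nucleotide bias** — for sites i ∈ {−3, −2, −1, 4, 5, 6} around the
  start codon, ln p_pos(x_i) / p_neg(x_i) of the observed nucleotide x (the
  Kozak-context signal, kept per site);
* **codon usage bias** — (1/n) Σ ln p_pos(C_i) / p_neg(C_i) over all n
  codons, where p(C) is codon count over encoding-amino-acid count;
* **hexamer score** — Σ ln f_pos(h) / f_neg(h) over in-frame hexamers
  (one-codon step);
* **Fickett position parameters** — per nucleotide,
  max(b1,b2,b3)/(min(b1,b2,b3)+1) of its counts at the three codon
  positions;
* ORF length, k-mer frequencies and (in the complete 1169-dim layout)
  gapped k-mer pairs.

Probability tables are fitted from the training split with additive
smoothing. A random forest on the 32-feature default schema (`"final32"`,
the shipped mRMR ranking of the 33 basic/TIS/in-frame features minus its
lowest-ranked member) is the default classifier; logistic regression, SVM
and gradient tree boosting are available behind the same interface, with
stratified 10-fold cross-validation, feature ablation, mRMR-IFS selection
and precision-targeted cutoff calibration (`choose_cutoff()`). Genome
candidates are filtered with per-start-codon cutoffs (stricter for weaker
start codons; AAG/AGG excluded outright), cleared of candidates contained
in annotated same-strand CDS intervals, annotated with overlapping gene
biotypes, and written as FASTA + BED6 + TSV.

## Worked example

```r
library(smorfcp)

sets  <- generate_training_sets(synth_config(n_pos = 300, n_neg = 300, seed = 42))
split <- assemble_datasets(sets$pos, sets$neg, seed = 42)
model <- train_smorf_model(split$train[split$train$label == "positive", ],
                           split$train[split$train$label == "negative", ],
                           schema = feature_schema("final32"), seed = 42)
model
#> <smorf_model> method=RF features=32 schema=final32 cutoffs=8

scores <- predict_scores(model, split$test)
truth  <- split$test$label == "positive"
m <- compute_metrics(confusion(scores, truth, 0.5))
sprintf("test ACC %.3f  MCC %.3f  SN %.3f  SP %.3f", m$ACC, m$MCC, m$SN, m$SP)
#> "test ACC 0.970  MCC 0.940  SN 0.970  SP 0.970"
curve_and_auc(scores, truth, "roc")$auc
#> 0.997
```

The held-out accuracy/MCC say how well the forest separates the two
synthetic classes at the 0.5 cutoff; the ROC area is the probability that a
random positive outscores a random negative. Scanning a toy genome then
applies the per-start-codon cutoffs:

```r
toy   <- generate_toy_genome(n_contigs = 1, contig_len = 5000,
                             planted = data.frame(start_codon = c("ATG", "CTG"),
                                                  codons = c(30, 20),
                                                  strand = c("+", "-")),
                             seed = 42)
cands <- scan_smorfs(toy$genome, min_codons = 11, max_codons = 101)
nrow(cands)
#> 1005
kept <- score_and_filter(cands, model)
nrow(kept)
#> 1
```

A 5 kb random contig yields 1005 raw start-to-stop candidates; the
stringent cutoffs (0.780 for ATG/CTG, up to 1.0 for the weakest starts)
reject all but one — the precision-first behaviour a genome-wide scan
needs, since its raw candidate sets run to millions. `emit_database(kept,
"out/db")` writes the FASTA/BED6/TSV triple; `remove_within_cds()` and
`annotate_overlap()` slot in between when an annotation is available.

A command-line wrapper ships at `inst/cli/smorfcp`
(`smorfcp synth|prep|featurize|train|select|evaluate|scan`, JSON config
support, versioned sidecars next to every artifact).

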