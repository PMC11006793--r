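---
title: "Modelling smORF coding potential and scanning genomes"
author: "smorfcp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling smORF coding potential and scanning genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smorfcp)
```

## The problem

Small open reading frames (smORFs) — here, ORFs of at most 101 codons
including the stop — encode microproteins that standard gene annotation
largely misses: they are too short for conservation-based gene finders, and
coding-potential tools tuned on full-length transcripts lose most of their
signal (ORF coverage, long hexamer runs) at this scale. `smorfcp` builds a
binary classifier that separates genuinely coding smORFs from length-matched
ORFs found in non-coding RNA, and then applies that classifier in a
six-frame scan of a genome to nominate novel smORF candidates, including
ones with near-cognate (non-ATG) start codons.

The two sequence classes the model is trained on are:

* **positive** — annotated mRNA CDSs of ≤ 101 codons, each prefixed with the
  three transcript nucleotides upstream of the start codon (sites −3, −2,
  −1);
* **negative** — the maximal ATG-initiated ORF extracted from each
  non-coding transcript, same length bound and the same upstream context
  convention.

All records share one container (`orf_dataset`), one invariant set (frame,
terminal stop, no internal stop, 3-letter upstream context) and one FASTA
convention (`upstream3` + `orf_seq` concatenated), so training data read
from disk and candidates produced by the genome scanner are interchangeable.

## Features

Encoding is parameterized by class-conditional probability tables fitted on
the training split only (`fit_feature_tables()`), with additive smoothing
(pseudocount 1 on every cell) so every log ratio below is finite even for
codons or hexamers unseen in training.

* **TIS nucleotide bias** (6 values): for each site
  $i \in \{-3,-2,-1,4,5,6\}$ around the start codon (positions 4–6 are the
  codon after the start), $\ln\, p_{\mathrm{pos}}(x_i)/p_{\mathrm{neg}}(x_i)$
  for the observed nucleotide $x$. This is the Kozak-context signal —
  purine at −3 and G at +4 mark efficient initiation — kept per-site rather
  than summed because the information content differs strongly between
  sites. An `N` at a site contributes 0 (both classes at 1/4).
* **Codon usage bias** (1 value): the mean over all codons, stop included,
  of $\ln\, p_{\mathrm{pos}}(C_i)/p_{\mathrm{neg}}(C_i)$, where $p(C)$ is
  codon count over encoding-amino-acid count (the three stops form one
  class). A mean, so it does not scale with length.
* **Hexamer score** (1 value): the **sum** over in-frame hexamers (ORF
  positions 1, 4, 7, …, one codon step) of the log frequency ratio. A sum by
  design — length itself carries coding evidence, and the hexamer score is
  the deliberately length-correlated in-frame feature.
* **Fickett position parameters** (4 values, order T, A, C, G): per
  nucleotide, $\max(b_1,b_2,b_3)/(\min(b_1,b_2,b_3)+1)$ of its counts at the
  three codon positions — the classic TESTCODE periodicity measure, here the
  position component only (no content component, no lookup weighting).
* **ORF length** (codons, stop included), **1-mer/2-mer** sliding-window
  frequencies, and, in the complete layout, **3-mer/4-mer** and gapped pairs
  (g-gap: nucleotide pairs separated by g bases, 16 patterns; g-bigap:
  dinucleotide pairs, 256 patterns; g ∈ {1,2,3}).

Three schemas fix the vector layout: `"complete"` (1169 = 33 + 64 + 256 +
3·16 + 3·256), `"reduced33"` (the 33 basic + TIS + in-frame features), and
`"final32"` — the reduced set ordered by the shipped mRMR ranking with its
lowest-ranked member (the TT dinucleotide frequency) removed. `"final32"`
is the default for trained models; the shipped ranking lets users skip
re-running selection. Natural logarithms are used throughout (any base only
rescales features).

## Models and evaluation

`train_classifier()` exposes four families behind one interface — logistic
regression, SVM (RBF), random forest, gradient tree boosting — each emitting
a positive-class score in [0, 1]; random forest with `mtry = sqrt(p)` is the
default, as it is the best performer for this task. Evaluation uses
SN/SP/PRE/ACC/F1S, the harmonic mean of SN and SP (HM), MCC, and
trapezoid-integrated ROC and PR curves whose thresholds sweep all distinct
scores; the ROC area is exactly the Mann–Whitney probability of correct
ranking (ties counted half), which the tests verify by brute-force pair
counting. Numerical conventions: a 0/0 rate is reported as 0 and flagged; a
zero MCC denominator gives MCC 0; the decision rule is `score >= cutoff`
(ties positive). The PR curve puts recall on x and precision on y for
integration (axis labelling elsewhere is cosmetic).

`cross_validate()` runs stratified k-fold CV (shuffled index modulo k, so
per-class fold sizes differ by at most one) and — important for honesty —
re-fits the feature tables inside each fold on that fold's training part
only. Encoded features are functions of fitted probability tables; fitting
them once on all data would leak every held-out sequence into the features
it is scored with.

## Feature selection

Two routes shrink the 1169-dim vector:

* **Component ablation** (`ablate_components()`): repeatedly drop the
  feature block whose removal yields the best cross-validated subset
  (highest mean MCC, ties by ACC then name). At desk scale this reproduces
  the qualitative result that the k-mer/g-gap blocks are dispensable while
  TIS and in-frame features are not.
* **mRMR-IFS** (`mrmr_rank()` + `ifs_select()`): features are discretized
  into 3 bins at mean ± one SD (classic mRMR practice), ranked by the
  mutual-information-quotient rule (relevance over mean redundancy with the
  already-selected set, MI in nats, ties by feature name), then nested
  top-i subsets are cross-validated.

Two numerical choices here were forced by small-sample behaviour and are
deliberate deviations from the textbook recipes:

1. **Relevance screening.** The MIQ quotient divides two MI estimates. For
   an uninformative feature both numerator and denominator are near zero,
   and their ratio is numerically unstable — on 1000 samples a pure-noise
   feature can outrank a genuinely informative feature that happens to be
   redundant with the first pick. `mrmr_rank()` therefore applies a G-test
   screen ($2N \cdot \widehat{MI}$ is asymptotically $\chi^2$ under
   independence) at `alpha = 0.001` and zeroes non-significant relevance.
   With exact MI this screen changes nothing; at finite n it removes the
   pathology.
2. **The one-standard-error rule for `best_size`.** Once the informative
   features have entered, the incremental CV-MCC curve is a plateau whose
   fluctuations are pure estimation noise, so a strict argmax lands
   arbitrarily deep in the plateau. `ifs_select()` therefore picks the
   smallest subset whose mean MCC is within one standard error of the best
   — the same parsimony rule penalized-regression tuning uses — and keeps
   the strict argmax available via `rule = "max"`. All subset sizes share
   one fold assignment so the curve reflects feature content, not fold
   luck.

## Cutoff calibration and genome scanning

`choose_cutoff()` returns the smallest threshold whose precision on a
held-out labelled score set reaches a target, or 1.0 ("reject everything")
when no threshold qualifies. Scanning a genome proposes millions of
candidates, so precision is the operative metric, and weaker start codons
warrant stricter cutoffs. The shipped `default_cutoff_map()` encodes that
policy by start-codon efficiency rank: 0.780 for ATG and CTG (precision
target 0.95), 0.968 for GTG/ACG (target 0.99), 1.000 for TTG/ATT/ATC/ATA,
with AAG and AGG absent from the map — absence means the codon is excluded
outright, which is exactly the reject-all limit of the calibration.

`scan_smorfs()` enumerates, on both strands and all three frames, every
span from a configured start codon to the nearest in-frame stop with a
codon count in [11, 101] by default. All nested starts sharing a stop are
reported (`longest_only = FALSE`), since a scan for candidate initiation
sites has no reason to privilege the longest; coordinates are always
forward-strand 0-based half-open; the upstream context is read strand-aware
and `N`-padded at contig edges; codons containing `N` are never starts or
stops and candidates containing `N` are discarded (the probability tables
are defined over A/C/G/T). Downstream, `remove_within_cds()` drops
candidates wholly contained in a single same-strand annotated CDS interval
— CDS features are per-exon, so single-interval containment is the
operative test, and strandedness matters because an antisense ORF under a
CDS is not redundant with it. `annotate_overlap()` assigns overlapping gene
biotypes with precedence protein_coding > lncRNA > pseudogene >
transcribed_pseudogene > other, and `emit_database()` writes the FASTA /
BED6 / TSV triple. `translate_seps()` renders peptides with the first
residue forced to methionine for every start codon, matching initiator-tRNA
decoding of near-cognate starts.

## Synthetic data: what it emulates and what it does not

`generate_training_sets()` emulates the two contrasts the encoders target:
a skewed synonymous-codon distribution (one codon per family up-weighted
`1 + 3*strength` : 1) and a Kozak-like upstream context (P(A or G at −3)
and P(G at site 4) equal to `0.25 + 0.5*strength`). Negatives are
uniform-codon ATG-initiated ORFs. At `strength = 0` the classes are
exchangeable by construction — a null in which cross-validated AUC must sit
near 0.5 — and at `strength = 1` they are strongly separable (CV AUC above
0.99 with the reduced schema). Lengths are uniform on 11–101 codons in both
classes. Deliberately absent: GC/isochore structure, splicing, hexamer
autocorrelation beyond what codon skew induces, and any length difference
between classes. Passing tests on these data therefore demonstrate that the
pipeline recovers planted signal of the kind it models — not that the
shipped defaults reach any particular accuracy on real transcripts, which
depends on real training data.

`generate_toy_genome()` plants ORFs (built without internal in-frame stops)
onto random contigs, records their intervals as truth, and can cover chosen
ones with decoy CDS features; scanner recovery of every planted interval is
asserted across a 10-seed suite. `generate_feature_matrix()` plants
mean-shifted informative features (2 SD shift by default) among
standard-normal noise for the selection tests.

## Problem sizes and numerical conventions

The test-suite and acceptance runs use desk-scale sizes chosen once:
500/class records for the null and separable CV checks (10-fold, default
forest), 10 random two-contig genomes (~9 kb each, one contig with 4%
ambiguous bases) scanned under two start-codon/length configurations for
scanner–oracle equivalence, 1000 random confusion
matrices for the metric oracle, and 2 informative + 8 noise features at
500/class for selection recovery. Redundancy removal uses global
Needleman–Wunsch identity (matches over alignment length, gaps included)
with thresholds 0.9/0.9, greedy longest-first with lexicographic-id
tie-break; it is exact and quadratic, adequate at these scales (an external
clusterer would be the choice for hundreds of thousands of sequences).
Every stochastic operation takes an explicit seed (default 42), and the CLI
(`smorfcp_run()`, subcommands `synth`, `prep`, `featurize`, `train`,
`select`, `evaluate`, `scan`) writes a sidecar JSON with the package
version and an options hash next to every artifact.

## Known limitations

* The model is only as species-specific as its training data; with few
  known coding smORFs a species cannot support a reliable model.
* The 101-codon bound counts the stop codon (so ≤ 100 residues); the
  ncRNA-side "maximal ORF" is read as ATG-initiated, the conventional
  reading consistent with the positive set's annotated starts.
* CDS containment is tested per annotation interval, not against spliced
  CDS models; a candidate spanning an intron is retained.
* The scanner holds one contig in memory at a time and its output is
  identical whether a genome is processed whole or contig by contig, so the
  candidate stream can be scored and filtered per contig when the unscored
  candidate set for a full genome would be too large to hold at once.
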