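---
title: "Extracting mutation-gene and mutation-drug relations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting mutation-gene and mutation-drug relations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Precision oncology needs curated links between point mutations, the genes
that carry them, and the drugs whose efficacy they predict (the canonical
example being BRAF V600E and vemurafenib in melanoma). These links are
reported in the literature far faster than human curators can collect
them. `mutrelex` implements a relation-extraction pipeline for
entity-annotated abstracts: given text in which mutations, genes, drugs,
diseases and cell lines have already been tagged (PubTator-style input —
named-entity recognition itself is out of scope), it classifies candidate
mutation-gene and mutation-drug pairs as related or not, at two
granularities:

* **Document level** — every pair of a unique mutation and a unique
  partner entity in a document is a candidate (m × n pairs); a pair is
  true if the relation is asserted anywhere in the document. A feature
  vector feeds a random-forest (or CART decision-tree) classifier.
* **Sentence level** — a candidate is a mutation and a partner co-occurring
  in one sentence; a convolutional sentence classifier decides whether the
  sentence asserts the relation.

Because the real corpora behind this task (curated full-text relation
corpora, ClinVar/COSMIC/PharmGKB joins over PubMed, a live PubMed-scale
entity search engine) cannot ship with a package, `mutrelex` includes a
seeded synthetic generator that reproduces the *structure* of those
resources, and every claim the test suite makes is a property of the
method on those generated conditions — not a reproduction of published
absolute scores.

## Background-knowledge features from a co-occurrence index

A domain expert who sees "V600E" near "melanoma" immediately recalls that
BRAF is the relevant gene. The pipeline mimics this with a search index
over a background corpus: `build_index()` records, per document, the
lower-cased word postings and per-kind entity occurrence counts.
`retrieve()` answers conjunctive queries with an optional OR-group, and
`score_entities()` ranks the entities of a target kind found in the
retrieved documents by

    score(e) = sum_d count(d, e) * log(1 + N / df(e)),

a transparent tf-idf-style weighting (document frequency `df`, corpus size
`N`). The live search engine this replaces uses an undisclosed proprietary
score; only relative magnitudes matter to the downstream classifiers, so
any monotone co-occurrence weighting serves. Four query strategies produce
the four score features of a candidate (mutation, partner) pair, with the
context C = the other entities near the mutation, *excluding entities of
the partner's own kind* (a drug in the context distorts the score of the
candidate drug rather than adding information):

| feature | query |
|---|---|
| `bssm` | mutation alone |
| `bssa` | mutation AND all of C |
| `bsso` | mutation, with C as an OR group |
| `bssao` | mean over c in C of (mutation AND c) |

`bssao` uses the mean rather than the sum so its scale does not grow with
context size. The mutation term is required in every strategy. Sentence
context is used for sentence-level candidates, all document entities for
document-level ones.

## Distance and frequency features

Four simple document statistics complete the document-level feature
vector: `ntds`, the number of sentences where the pair co-occurs; `tdfs`,
the partner's mention count; `odfs`, the mention count of the most
frequent same-kind rival; and `dmcs`, a binary flag — is the mutation's
nearest partner-kind mention this partner, in the same sentence? Design
choices the literature leaves open, fixed here once: co-occurrence is
counted at sentence granularity; "nearest" means smallest distance of
span midpoints with ties broken leftward; and `dmcs` is evaluated per
candidate, so candidates sharing a mutation get discriminative values
rather than one shared flag.

## Mutation normalization and the residue filter

`normalize_mutation()` maps one-letter, three-letter and `p.`-prefixed
protein substitutions ("Val600Glu", "p.Thr790Met") to the canonical
`XnY` form; DNA-level mentions (`c.1799T>A`) pass through unparsed and are
excluded from gene-pair datasets, because the wild-type check below cannot
be applied to them. `seq_filter()` keeps a (mutation, gene) pair only when
residue `n` of the gene's protein is `X` (1-based indexing, the standard
protein convention). This is the classical wild-type residue filter used
to purge spurious mutation-gene co-occurrences.

## Distant supervision

`build_pair_sentence_dataset()` builds sentence training sets without
manual labels. Positives are sentences whose (mutation, partner) pair is
recorded in a curated relation table for that document and — for genes —
passes the residue filter. Negatives are co-occurring pairs absent from
the table (and from any supplied known-relations list) and — for genes —
failing the residue filter. A sentence enters the dataset at most once,
and a sentence holding any positive pair is never used as a negative;
this keeps the two sets disjoint and avoids duplicated near-identical
training rows.

## The convolutional sentence classifier

Each candidate sentence is encoded with entity mentions collapsed to
single tokens (so the embedding channels are token-aligned). Each token
carries:

* a word embedding (300-d by default),
* a 10-d *type* embedding over {target mutation, target gene, target
  drug, other mutation/gene/drug, disease, cell line, plain, pad},
* two 10-d *position* embeddings indexed by the token's offset from the
  target mutation and from the target partner, clipped to the window.

Convolution filters of widths 3/4/5 (100 maps each) with ReLU run over
the 330-d token representations; max-over-time pooling yields a 300-d
sentence vector; the four search scores (standardized with training-set
mean/variance) are concatenated after pooling — the single fusion point
consistent with treating them as sentence-level evidence — followed by
dropout (keep 0.5) and an affine softmax over {false, true}. Widths, map
counts, dropout and batch size (50) follow the widely used convolutional
sentence-classification defaults. The optimizer (Adam, 1e-3), epoch count
and maximum sentence length (30 tokens) are package defaults, chosen once:
on the synthetic benchmark the loss plateaus within two epochs, so the
benchmark protocols train for two; the package default is three.

The network is implemented directly in base-R matrix algebra (no deep
learning framework dependency): the convolution is computed as a sum of
shifted matrix products, gradients are scattered into the embedding
tables with `rowsum()`, and the backward pass is verified against central
finite differences in the test suite. Training is mini-batch, fully
seeded, and reproducible on a single compute thread. Word embeddings can
be initialized from vectors trained with `train_word_vectors()` — a
skip-gram negative-sampling trainer (window 5, 5 negatives, unigram^0.75
sampling, minimum frequency 5, multi-word entities merged to single
tokens first) — or loaded from word2vec text/binary files; all embeddings
are fine-tuned either way.

Sentences longer than the window are truncated to a span centered between
the two targets (both targets always kept); out-of-vocabulary tokens map
to a shared unknown id; padding has its own reserved word/type/position
ids.

## The synthetic study conditions

`generate_corpus()` is first-class, tested code; its defaults define the
conditions under which every empirical property in this package is
asserted:

* lexicons of 25 genes, 25 drugs, 60 mutations (corpus-size benchmarks
  scale these up), 8 two-word diseases, 6 cell lines;
* random 400-residue proteins; each mutation's wild type is read off its
  true gene, so every true mutation-gene pair passes the residue filter;
  decoy pairs fail it at a configurable rate (default 0.8 — residues
  match by chance at roughly 1/20, and the generator plants or removes
  matches to hit the configured rate);
* mutation-gene truth is 1:1; about 60% of mutations carry 1–3 drugs
  (mixed 1:1 and 1:n), mirroring the structural asymmetry that makes the
  drug task harder;
* 120 documents of 6 sentences (first sentence is an intro); each later
  sentence slot expresses a true relation with probability 0.5 (positive
  templates carry trigger phrasing — "conferred sensitivity to",
  "drives" — and distractor entities) or a decoy co-mention with neutral
  phrasing; 10% of positives use trigger-free phrasing;
* document-level labels follow the any-sentence rule;
* a 300-document background corpus in which true pairs co-occur 4× more
  often than random pairs — the signal the search-score features read.

What the generator does **not** emulate: real linguistic variety (a small
closed template set), real token distributions, nested/overlapping
mentions, discontinuous mentions, abbreviation ambiguity, and relation
phrasings unseen in training. Passing tests therefore demonstrate that
the machinery is correct and that each component contributes the signal
it is designed to carry — not that these accuracy levels transfer to
PubMed text.

## Evaluation protocols

Document level: balanced stratified 10-fold cross-validation — folds are
assigned stratified by class (a guard the source protocols leave
unstated, so small balanced sets cannot produce empty-class folds), then
both the training and the test portion of each fold are balanced by
down-sampling negatives. Sentence level: repeated random sub-sampling —
per repetition a fresh balanced test set (100+100 by default) is drawn,
the remainder balanced, and the model retrained from scratch; draws are
independent across repetitions. Precision/recall/F1 define zero divisions
as 0 so averaging is total. The no-learning baseline predicts every
candidate positive; on balanced candidates that is exactly P = 0.5,
R = 1, F1 = 2/3, the floor both trained models must clear.

`export_relation_table()` turns predicted-positive sentences into a
relation table sorted by probability (deduplication keeps the
highest-probability row per (document, mutation, partner) triple), and
`compare_to_gold_list()` partitions an external gold list into found /
never co-occurring in a sentence (undetectable by a sentence-level
extractor) / other misses.

## Problem sizes used by the shipped benchmarks

The acceptance suite and `scripts/acceptance.R` state their conditions
explicitly: document-level runs use the default 120-document corpus
(~400 balanced candidates over the two tasks); the main sentence-level
benchmark uses a 1000-document corpus, a 1600+1600 example pool, 5
sub-sampling repetitions with 100+100 test draws and 1500+1500 training
sentences; the ablation comparisons (scores on/off, pre-trained vs random
embeddings) use 400-document corpora with 600+600 pools across 5 seeds;
the acceptance script uses 600-document corpora with 1000+1000 pools and
3 repetitions. These sizes were chosen once as the smallest at which the
compared quantities are stable to within the tolerances asserted.

## Known limitations

* No DNA/RNA-level HGVS parsing, insertions, deletions or frameshifts —
  substitutions only.
* Mutations are identified per document by their canonical string; two
  same-named substitutions in different genes within one document are not
  disambiguated.
* The index scoring formula is a declared stand-in, not the proprietary
  score of any live search engine; absolute score values are not
  comparable to published ones.
* Single-threaded, CPU-only training sized for corpora of thousands of
  sentences, not millions.
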