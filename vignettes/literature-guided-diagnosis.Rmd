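---
title: "Literature-guided differential diagnosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-guided differential diagnosis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litddx)
```

## The problem and the model

Supervised diagnosis classifiers need labeled notes per diagnosis, but
clinical datasets are heavily long-tailed: a handful of conditions have
thousands of notes while hundreds have one or none. `litddx` implements a
retrieval-based alternative that needs no labeled training data. A patient
note is treated as a query against a corpus of concept-annotated literature
abstracts, and the diagnoses mentioned in the best-matching abstracts form
the differential.

The pipeline is:

1. **Query filtering.** The note is reduced to its recognizable medical
   terms by exact dictionary matching against a concept vocabulary
   (`filter_query()`). Everything else — stop words, filler, non-clinical
   text — is discarded.
2. **Retrieval.** The filtered query retrieves the top $N$ abstracts
   (default $N = 100$) from a BM25 inverted index (`search_index()`).
3. **Label generation.** For every concept $c$ occurring in the concept
   dictionary of any retrieved abstract, its term frequency
   $\mathrm{TF}(c)$ is the number of retrieved abstracts whose concept set
   contains it — document-level recurrence, not within-document counts
   (`aggregate_tf()`).
4. **Ranking.** Candidates are scored
   $\mathrm{TFIDF}(c) = \mathrm{TF}(c) \cdot \ln(N_{\mathrm{corpus}} /
   \mathrm{df}(c))$, where $\mathrm{df}(c)$ is the number of indexed
   abstracts containing $c$ (`rank_diagnoses()`). Rank 1 is the most
   likely diagnosis.

In evaluation mode the tallied concepts are first restricted to the
benchmark's candidate label set; this mirrors how a retrieval system is
compared fairly against closed-set classifiers. An abstract-coverage
threshold (`eligible_diagnoses()`, default 100 abstracts) removes candidate
diagnoses too rare in the corpus to be rankable from literature.

### Ensembling

A supervised classifier, where training notes exist, sees patterns the
literature does not. `rrf_fuse()` merges the two rankings with reciprocal
rank fusion: $\mathrm{score}(c) = \sum_{r \in R(c)} 1/(k + r)$ with
$k = 60$, the standard near-optimal setting. The modification is a
training-count fallback: a diagnosis with fewer than `min_train_samples`
(default 2) training notes takes only the retrieval member's term, because
the supervised member cannot be trusted on (near-)unseen classes, and it
cannot rank unseen classes at all.

### Evaluation

`reciprocal_rank()` scores a query $1/\mathrm{rank}$ of the best-ranked
acceptable gold concept (several golds may be acceptable for split cases),
0 if absent; `mean_reciprocal_rank()` averages over queries, and
`mean_average_precision()` computes standard label-level AP.
`stratified_mrr()` reports MRR within training-note-count bins
($\{0\}$, $(0,10]$, $(10,50]$, ..., $(750,\infty)$) — on long-tailed
benchmarks aggregate MRR hides exactly the zero- and few-shot regimes this
method targets.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `top_n` | 100 | abstracts retrieved per query |
| `k1`, `b` | 1.2, 0.75 | BM25 term-saturation and length normalization (Lucene practical defaults) |
| `min_abstracts` | 100 | abstract-coverage threshold on candidate diagnoses (use small values on small corpora) |
| `k` | 60 | RRF rank damping |
| `min_train_samples` | 2 | fallback threshold ("more than one training sample") |
| `smooth` | `FALSE` | IDF form `ln(N/df)` vs `ln((N+1)/(df+1))` |

## Design choices where the design was open

* **Exact dictionary matching, not approximate concept extraction.** The
  reference approach for clinical concept recognition is approximate
  string matching against a licensed metathesaurus with tunable similarity
  thresholds. Those resources are license-restricted and the thresholds
  unpublished, so recognition here is exact greedy leftmost-longest
  matching over token boundaries, case- and whitespace-insensitive, with
  no stemming. This is deterministic and testable against a brute-force
  span-enumeration oracle, at a declared fidelity cost: paraphrases and
  inflections of a synonym are not matched.
* **IDF for ranking.** The ranking-side IDF has no canonical closed form
  in this setting; `ln(N/df)` over the whole indexed corpus is used, with
  unseen concepts guarded to score 0 rather than erroring (df := N), and a
  smoothed form available.
* **Fusion formula.** Standard RRF (sum of reciprocals) is the default;
  the algebraically different reading `1/(k + Σr)` is available as
  `fusion_form = "reciprocal_of_sum"`.
* **Tie-breaks** are total and documented everywhere ranks are produced:
  retrieval ties by ascending `doc_id`; TF-IDF ties by higher TF then
  ascending concept id; fusion ties by better retrieval rank then
  ascending concept id. Reciprocal-rank evaluation is meaningless without
  deterministic ranks.
* **Degenerate inputs.** A note with no recognizable medical terms is a
  hard "degenerate query" error (the caller decides what to do); a
  candidate filter that removes every tallied concept returns an empty
  ranking with a warning (the query then scores RR 0); empty corpora and
  empty hit lists are errors.
* **Index persistence** stores the manifest plus per-abstract records
  (including precomputed concept sets) and deterministically rebuilds the
  inverted index on load, guaranteeing save/load round-trips reproduce
  identical retrieval results.

## The synthetic world

`generate_world()` emulates the structure of a long-tailed clinical
benchmark: `n_diagnoses` diagnosis concepts each with a signature of
`signature_size` symptoms; abstracts per diagnosis and notes per diagnosis
follow truncated Zipf profiles (`zipf_counts()`, tail floored at 1 note so
singleton diagnoses exist); each abstract names its diagnosis and a random
~70% subset of the signature plus occasional off-signature noise; each
note carries a sample of its gold signature (default 80%), `n_distractors`
off-signature symptoms, and `filler_rate` out-of-vocabulary filler tokens.
`symptom_overlap` shares a fraction of the signature with a paired
confounder diagnosis, making the world controllably confusable.
`split_notes()` applies the long-tailed protocol: singleton diagnoses go
entirely to test (training count 0 — the zero-shot bin), 2–4-note
diagnoses reserve exactly one test note, and diagnoses with ≥ 5 notes are
split 70:15:15 with rounding that favors the test set so every such
diagnosis is testable. `noisy_oracle_ranker()` stands in for a fine-tuned
supervised member: it never ranks unseen diagnoses, and places the gold at
rank 1 with probability `quality(train_count)` (default
`min(0.98, n/(n+2))` — weak at 1–3 notes, strong on well-represented
diagnoses), otherwise at a uniform rank in `[2, n_diagnoses]`.

Two generator choices deserve a note:

* **Symptom surface forms are token-unique** (`sympt017`, `sgn017`).
  An earlier multi-word scheme (`symptom 017`) leaked a shared token into
  every symptom, which at desk scale (hundreds of abstracts, top-100
  retrieval) acts as hidden symptom overlap: every abstract matches every
  query weakly, and frequent diagnoses flood the retrieved set. That
  violated the declared semantics of `symptom_overlap = 0`, so symptom
  tokens were made unique. Diagnosis names stay multi-token
  (`disease 003`, `d003 disorder`), so greedy longest-match is still
  exercised end to end.
* **Default sizes** (50 diagnoses, 400 symptoms, Zipf exponent 1.5,
  abstract head 60/floor 3, note head 400/floor 1) give ~240 abstracts and
  ~930 notes — a corpus a laptop indexes in under a second while still
  exhibiting a genuine head/tail contrast.

What the generator does **not** emulate: real clinical prose (notes are
bags of symptom terms), negation and temporality, coding-system structure,
synonym ambiguity across concepts (except where tests construct it), and
corpus scale. A green synthetic-recovery test therefore establishes that
the pipeline's mechanics are correct and that its signal degrades
monotonically with confusability — not that any particular MRR would be
attained on real notes against a real literature index.

## Numerical notes

BM25 uses `idf(t) = ln(1 + (N - df_t + 0.5)/(df_t + 0.5))`, which is
strictly positive for df ≤ N, so "score > 0" cleanly separates documents
sharing at least one query term from the rest. Scores are compared
exactly for tie-breaking; structurally identical documents produce
bit-identical scores, and near-ties are resolved by genuine score order.
In fusion, score differences at large `k` shrink like `1/k^2` but remain
representable well past `k = 10^9`; the rank tie-break only engages on
exact equality (e.g. mirrored ranks).

## Known limitations

Exact matching misses lexical variants; the ranker has no notion of
concept semantics (a symptom can outrank a disease — candidate filtering
is what confines output to diagnoses); IDF is computed on the same corpus
retrieval runs against, so corpus composition biases both; and the fusion
fallback trusts the retrieval member entirely below the training
threshold, which is only sensible when the retrieval member is usable for
rare classes — exactly the regime this design targets.
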