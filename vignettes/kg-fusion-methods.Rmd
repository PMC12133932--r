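---
title: "Knowledge-graph fusion for syndrome classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph fusion for syndrome classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kgfuse` classifies TCM electronic medical records (EMRs) into syndrome
categories by fusing two representations of a record: a text encoding of
its formatted fields and a knowledge vector aggregated from a medical
knowledge graph. This vignette documents the model, the tunable parameters,
the synthetic world the tests run in, and the numerical and design choices
that the code makes where the method description left them open.

## 1. The model

**Graph.** A knowledge graph `KG = (V, R)` of typed nodes under a fixed
schema: eleven entity types, of which Syndrome (4 attributes), Symptoms (5)
and Herb (5) carry full attribute sets, and nine typed relation signatures
(`Syndrome –Has_symptom→ Symptoms`, `Treatment –Common pharmaceuticals→
Drugs`, ...). Schema validation rejects any triple outside these
signatures. Multi-source fusion merges nodes equal on
`(entity_type, canonical_name)`; the cleaning pipeline first splits
composite labels on a bilingual connective lexicon (and/or/with,
enumeration commas, 和/及/并/伴/、) and rewrites synonym surfaces to
canonical vocabulary terms with an Aho–Corasick automaton using
leftmost-longest matching.

**Node embeddings.** DeepWalk: from every node, `r` truncated random walks
of maximum length `T`; at each step the successor is drawn uniformly from
the current node's neighbors, and a walk ends early at a node without
neighbors (no restart). The walk corpus trains a skip-gram model with the
*full softmax*

$$P(u \mid w) = \frac{\exp(V_u \cdot V_w)}{\sum_{v \in V} \exp(V_v \cdot V_w)}$$

maximized by minibatch SGD over (center, context) pairs within a window.
Negative sampling and hierarchical softmax are deliberately absent: at the
graph sizes this package targets (thousands of nodes) the exact objective
is affordable and testable — the suite checks the analytic gradient of
$\log P(u\mid w)$ against finite differences and the normalization of the
context distribution exactly.

**Entity recognition.** Structured records are tagged by an LSTM-CRF,
`Y = CRF(LSTM(X))`, over BIO labels for four mention types (symptom,
disease, syndrome, chief complaint). The CRF layer is exact: forward
log-partition, forward–backward marginals for training, Viterbi decoding
with ties broken toward the lowest label index. Semi-structured extraction
is a backend contract; the bundled backend is a deterministic gazetteer
matcher, and a stub documents the prompt template a hosted LLM backend
would use (no network code ships).

**Linking and aggregation.** A mention links by exact canonical-name match
first; the semantic fallback (a sentence-embedder contract; tests use a
deterministic character-n-gram hashing embedder) is invoked *only* on
failure — the suite proves this with an instrumented call counter. The
fallback accepts the top-1 cosine similarity if it reaches `tau`. Linked
node vectors combine by the frequency-weighted mean
$V_{kg} = \sum_i f_i V_i / \sum_i f_i$ with record-local frequencies
$f_i$; when nothing links, $V_{kg}$ is the all-zero vector of the
configured dimension (default 384).

**Fusion and classification.** `S_w = Concat(Linear(V_kg), V_emrs)` by
default; AVG and WEIGHTED variants are provided (WEIGHTED learns two
non-negative weights normalized to sum one via a 2-way softmax). A linear
head with softmax produces class probabilities trained with cross-entropy.

## 2. Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `walk_length` | 20 | maximum DeepWalk step length |
| `walks_per_node` | 10 | walks started per node (unspecified upstream; exposed) |
| `window` | 5 | skip-gram context half-width (unspecified upstream) |
| `dimension` | 384 | knowledge-embedding size; the reference experiments find 384 best on their grid {64, 128, 384, 768} |
| `tau` | 0.5 | semantic-linking acceptance threshold; `tau = -1` always accepts top-1, large `tau` reproduces hard-match-only linking |
| batch / lr / wd / max len / epochs | 16 / 2e-5 / 0.02 / 128 / 10 | classifier training defaults, mirroring the reference transformer setup |

Two documented contradictions in the source material are resolved in favor
of its tables: embedding dimension 384 (not the prose's 128) and 10 epochs
(not the prose's 15); both remain configurable.

The desk-scale experiment harness overrides the optimizer settings
(lr 0.05, 12 epochs, no weight decay): a learning rate tuned for fine-tuning
a pretrained transformer cannot move a small randomly initialized encoder.
The `fusion_config()` defaults are untouched.

## 3. The synthetic world

The generator (`synth_config`, `generate_kg`, `generate_emrs`,
`generate_tagging_corpus`) emulates the *statistical structure* of a
syndrome corpus, not its language:

- `S` syndrome classes, each with a symptom profile; adjacent classes share
  `symptom_overlap_rate` of their symptoms (chained, so high overlap makes
  symptoms ambiguous across several classes). Two adjacent classes share
  one disease name, so the disease field alone never identifies the class.
- each symptom gets a fixed number of synonym surface forms that always
  enter the dictionary/gazetteer; `synonym_rate` governs how often a
  rendered mention uses one. (The module contract sketches "synonyms
  emitted at `synonym_rate`"; rate-of-use is the dial that actually moves
  linking difficulty, so that is what the knob controls.) Synonym surfaces
  are single fused tokens (`achingsx01v3`): opaque to a word-level text
  encoder but lexically close to the canonical name at the character-n-gram
  level, mirroring real clinical writing where most phrasings of a symptom
  are rare but recognizable.
- class sizes are balanced or follow a geometric profile
  `round(largest * ratio^(k-1))`, emulating the extreme imbalance of real
  syndrome corpora (largest class thousands of records, smallest a few
  dozen).

Presets instantiate the scenarios the evaluation harness needs: `clean`
(everything exact-matches), `synonym-heavy` (the semantic fallback carries
the signal), `complementary-signal` (overlap 0.75, 12 variants per symptom,
60 records/class: text alone and knowledge alone are both partial) and
`text-sufficient`. A green ablation test therefore establishes the
*qualitative orderings* — fusion ≥ either branch alone; with-fallback ≥
hard-match-only — under these constructed conditions. It does **not**
establish the absolute scores of the full-scale system, which depend on an
external corpus and a pretrained Chinese transformer, nor robustness to
real clinical language.

## 4. Numerical and design choices

- **Node identity for merging** is `(entity_type, canonical_name)` after
  normalization — the only key available. Attribute conflicts resolve
  keep-first and the discarded value is recorded on the fused graph
  (`attr(,"conflicts")`) for audit.
- **Walks treat triples as undirected** (configurable `directed = TRUE`):
  the adjacency definition is set-theoretic and symmetric treatment is the
  DeepWalk convention.
- **Node ids** are stable integers; every iteration order is sorted; all
  stochastic stages take explicit seeds and restore the caller's RNG state.
- **CRF ties** break toward the lowest label index at every backpointer, so
  an all-tie instance decodes to the lexicographically first path.
- **Zero-denominator macro metrics** contribute 0 with a warning — keeps
  macro precision/recall defined under extreme imbalance.
- **Knowledge vectors are L2-normalized in the harness** before fusion.
  The scale of skip-gram vectors is arbitrary (it depends on dimension,
  epochs and learning rate); normalizing puts the knowledge branch on the
  same footing as the bounded (tanh) text features so that neither branch
  is invisible at initialization. `aggregate_knowledge_embedding` itself
  returns the exact weighted mean — normalization is a harness step, and
  zero vectors stay zero.
- **Projection size**: CONCAT keeps the knowledge dimension
  (`Linear: kg_dim -> kg_dim`); AVG/WEIGHTED project to the encoder's
  hidden size, which their algebra requires.
- **Train/validation protocol**: 80/20 stratified split, seeded (none is
  specified upstream).
- **Tokenization**: word-level lowercase alphanumeric tokens for the
  synthetic English fixtures; character-level inputs work through the same
  interfaces for Chinese text.

## 5. Known limitations

- The text encoder contract ships only the desk-scale bag-of-embeddings
  implementation; plugging in a pretrained transformer is an integration
  exercise left to the user (the contract is four functions).
- Polysemous entities ("multiple meanings") are only handled through
  splitting and dictionary rewriting; ambiguous rewrites surface in the
  normalization report's rule trace rather than being resolved.
- The semantic fallback's hashing embedder is deterministic and
  character-based; it stands in for a sentence encoder and will not capture
  paraphrases with no lexical overlap.
- `run_ablation` and `sweep_kg_dimension` retrain from scratch per
  configuration; at production scale you would cache embeddings and links
  (the functions already accept precomputed graphs).
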