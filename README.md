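# kgfuse

Knowledge-graph-augmented text classification for Traditional Chinese
Medicine (TCM) **syndrome differentiation**: given an electronic medical
record (disease name, chief complaint, history), predict the syndrome
(*zheng*) category. Plain text classifiers struggle here because symptom
descriptions are highly redundant and variably phrased, and the label set is
extremely imbalanced. `kgfuse` compensates by injecting structured medical
knowledge: a syndrome-centred knowledge graph is cleaned, embedded, linked
against the record's symptom mentions, and fused with a text encoder.

The package is aimed at clinical-NLP researchers who want a fully offline,
testable re-implementation of the pipeline — every stage is a documented R
function with a deterministic synthetic-data generator standing in for
proprietary corpora.

## The pipeline

1. **Graph construction** (`kg_new`, `kg_add_nodes`, `kg_fuse`,
   `read_kg`/`write_kg`): typed nodes (Syndrome, Symptoms, Herb, Treatment,
   Disease, ...) and triples validated against a schema with nine relation
   signatures such as `(Syndrome, Has_symptom, Symptoms)`. Entity
   recognition for structured records uses an **LSTM-CRF** tagger
   (`train_tagger`), `Y = CRF(LSTM(X))`; semi-structured extraction is a
   pluggable backend with a deterministic gazetteer implementation
   (`rule_backend`).
2. **Cleaning** (`split_composite_label`, `normalize_term`,
   `merge_duplicate_nodes`): composite labels are split on a bilingual
   connective lexicon, and an **Aho–Corasick automaton** rewrites synonym
   surface forms to canonical vocabulary terms with leftmost-longest
   matching before duplicate nodes are merged.
3. **Representation** (`embed_graph`): DeepWalk — truncated uniform random
   walks (default length T = 20, 10 walks per node) feed a skip-gram model
   with a **full softmax** objective

   L = Σ_w Σ_{u∈N(w)} log P(u|w),  P(u|w) = exp(V_u·V_w) / Σ_v exp(V_v·V_w),

   producing node embeddings (default dimension 384) stored on the graph.
4. **Linking** (`link_mention`, `aggregate_knowledge_embedding`): exact
   ("hard") name match first; only on failure a sentence-embedder fallback
   picks the most cosine-similar node above a threshold τ. Linked node
   vectors are combined by the frequency-weighted mean
   V_kg = Σ f_i·V_i / Σ f_i; if no link succeeds V_kg is the 384-zero
   vector.
5. **Fusion classification** (`fusion_model`, `train_fusion`,
   `predict_fusion`): S_w = Concat(Linear(V_kg), V_emrs) (AVG and WEIGHTED
   variants available) followed by a linear head and softmax, trained with
   cross-entropy (defaults: batch 16, lr 2e-5, weight decay 0.02, max
   sequence length 128, 10 epochs). The text encoder is a contract; the
   bundled desk-scale encoder trains in seconds on a CPU.
6. **Evaluation** (`compute_metrics`, `run_ablation`,
   `sweep_kg_dimension`): accuracy and macro precision/recall/F1, plus
   harnesses mirroring the ablation and embedding-dimension experiments on
   synthetic scenarios.

## Worked example

```r
library(kgfuse)
sc <- scenario_preset("complementary-signal", seed = 7)
sc$bundle$kg
#> <knowledge_graph: 26 nodes, 36 triples>
run_ablation(sc, seed = 7)
#>       config   acc macro_f1 macro_precision macro_recall seed
#> 1  text-only 0.750    0.729           0.817        0.750    7
#> 2    kg-only 0.854    0.844           0.888        0.854    7
#> 3 fused-noST 0.854    0.853           0.871        0.854    7
#> 4      fused 0.854    0.853           0.856        0.854    7
```

The scenario renders most symptom mentions as rare synonym tokens, so the
text-only model degrades (ACC 0.750); linking canonicalizes the mentions
and the knowledge-only model does better (0.854); the fused model matches
the best single branch here and beats text-only by 10 points — the
qualitative ordering (fusion ≥ either signal alone, semantic fallback ≥
hard-match-only) that the full-scale system reports. Absolute scores from
the original large-scale corpus are out of scope: they require an external
dataset and GPU fine-tuning of a pretrained Chinese transformer.

## Command line

```sh
inst/cli/kgfuse simulate --preset clean --seed 7 --out fixtures/
inst/cli/kgfuse build-kg --in fixtures/kg.jsonl --out kg.graphml
inst/cli/kgfuse embed --kg fixtures/kg.jsonl --out kg.embedded.jsonl --dim 384 --seed 7
inst/cli/kgfuse link --kg kg.embedded.jsonl --in mentions.txt --out links.csv --tau 0.5
```

See `vignettes/kg-fusion-methods.Rmd` for the modelling assumptions, the
design of the synthetic scenarios, and known limitations.
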