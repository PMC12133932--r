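# Experiment harnesses: ablation over model configurations and a sweep over
# knowledge-embedding dimensions, run end-to-end on synthetic scenarios.

# Stratified train/validation split (80/20), seeded.
stratified_split <- function(labels, val_frac = 0.2, seed = 1L) {
  with_seed(seed, {
    val <- integer()
    for (k in unique(labels)) {
      idx <- which(labels == k)
      n_val <- max(1L, floor(length(idx) * val_frac))
      val <- c(val, sample(idx, n_val))
    }
    list(train = setdiff(seq_along(labels), val), val = sort(val))
  })
}

# Extract mentions from each record's text with the gazetteer backend and
# aggregate knowledge vectors under a given linker setup. Rows are
# L2-normalized by default: the scale of skip-gram vectors is arbitrary, and
# unit-norm knowledge vectors put the two fusion branches on a comparable
# footing (zero rows stay zero).
pipeline_vkg <- function(records, bundle, ekg, embedder, tau, dim,
                         normalize = TRUE) {
  backend <- rule_backend(bundle$gazetteer)
  texts <- vapply(records, function(r)
    paste(r$chief_complaint, r$history), "")
  out <- matrix(0, length(records), dim)
  methods <- character()
  for (i in seq_along(records)) {
    res <- extract_entities(texts[i], backend)
    men <- c(res$symptoms, res$syndromes)
    if (!length(men)) next
    links <- link_mentions(men, ekg, embedder, tau)
    methods <- c(methods, links$method)
    out[i, ] <- aggregate_knowledge_embedding(links, ekg, dim)
  }
  if (normalize) {
    nrm <- sqrt(rowSums(out^2))
    out <- out / pmax(nrm, 1e-12)
  }
  attr(out, "link_methods") <- methods
  out
}

train_and_eval <- function(records, vkg, split, n_classes, kg_dim,
                           fusion_method, config, hidden = 32L) {
  enc <- bow_encoder(hidden_size = hidden, embed_dim = 16L)
  model <- fusion_model(enc, n_classes, kg_dim, fusion_method, config)
  model <- train_fusion(model, records[split$train],
                        vkg[split$train, , drop = FALSE])
  preds <- vapply(split$val, function(i)
    predict_fusion(model, records[[i]], vkg[i, ])$label, 0L)
  truth <- vapply(records[split$val], function(r) r$label, 0L)
  list(model = model,
       metrics = compute_metrics(truth, preds, n_classes))
}

#' Ablation harness: text-only, knowledge-only, no-semantic-fallback, full
#'
#' Trains four configurations on one synthetic scenario with identical
#' seeds and splits: the text-only model (knowledge branch removed), the
#' knowledge-only model (text branch removed), the full model with the
#' semantic fallback disabled (failed exact matches yield the zero vector),
#' and the full model. Reports validation metrics per configuration.
#'
#' @param scenario a [scenario_preset()] result (or an equivalent list with
#'   `bundle` and `corpus`).
#' @param seed seed governing embedding, split and training.
#' @param kg_dim knowledge-embedding dimension for this run (desk-scale
#'   default 32; the production default elsewhere is 384).
#' @param tau semantic-linking threshold.
#' @param epochs,learning_rate training settings for the small test
#'   encoder.
#' @return data.frame with one row per configuration: `config`, `acc`,
#'   `macro_f1`, `macro_precision`, `macro_recall`, `seed`.
#' @export
run_ablation <- function(scenario, seed = 7L, kg_dim = 32L, tau = 0.35,
                         epochs = 12L, learning_rate = 0.05) {
  records <- scenario$corpus$records
  labels <- vapply(records, function(r) r$label, 0L)
  n_classes <- length(unique(labels))
  if (n_classes < 2) stopf("value error: need at least 2 classes")
  ekg <- embed_graph(scenario$bundle$kg,
                     walk_config(seed = seed),
                     skipgram_config(dimension = kg_dim, epochs = 3L,
                                     seed = seed))
  vkg_full <- pipeline_vkg(records, scenario$bundle, ekg,
                           hash_embedder(384L), tau, kg_dim)
  vkg_nost <- pipeline_vkg(records, scenario$bundle, ekg, NULL, tau, kg_dim)
  split <- stratified_split(labels, 0.2, seed)
  zero <- matrix(0, length(records), kg_dim)
  base_cfg <- function(...) fusion_config(epochs = epochs,
                                          learning_rate = learning_rate,
                                          weight_decay = 0, seed = seed, ...)
  runs <- list(
    `text-only` = list(vkg = zero, cfg = base_cfg(use_kg = FALSE)),
    `kg-only` = list(vkg = vkg_full, cfg = base_cfg(use_text = FALSE)),
    `fused-noST` = list(vkg = vkg_nost, cfg = base_cfg()),
    `fused` = list(vkg = vkg_full, cfg = base_cfg()))
  rows <- lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    m <- train_and_eval(records, r$vkg, split, n_classes, kg_dim,
                        "CONCAT", r$cfg)$metrics
    data.frame(config = nm, acc = m$acc, macro_f1 = m$macro_f1,
               macro_precision = m$macro_precision,
               macro_recall = m$macro_recall, seed = seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sweep over knowledge-embedding dimensions
#'
#' Re-embeds the graph at every requested dimension, relinks and retrains
#' the full model, and reports validation metrics per dimension. The default
#' grid is `{64, 128, 384, 768}`.
#'
#' @inheritParams run_ablation
#' @param dims positive integer dimensions to evaluate.
#' @return data.frame with one row per dimension.
#' @export
sweep_kg_dimension <- function(scenario, dims = c(64L, 128L, 384L, 768L),
                               seed = 7L, tau = 0.35, epochs = 12L,
                               learning_rate = 0.05) {
  if (!length(dims)) stopf("value error: dims must be non-empty")
  if (any(dims < 1)) stopf("value error: non-positive dimension")
  records <- scenario$corpus$records
  labels <- vapply(records, function(r) r$label, 0L)
  n_classes <- length(unique(labels))
  split <- stratified_split(labels, 0.2, seed)
  rows <- lapply(dims, function(d) {
    ekg <- embed_graph(scenario$bundle$kg, walk_config(seed = seed),
                       skipgram_config(dimension = d, epochs = 3L,
                                       seed = seed))
    vkg <- pipeline_vkg(records, scenario$bundle, ekg,
                        hash_embedder(384L), tau, d)
    m <- train_and_eval(records, vkg, split, n_classes, d, "CONCAT",
                        fusion_config(epochs = epochs,
                                      learning_rate = learning_rate,
                                      weight_decay = 0, seed = seed))$metrics
    data.frame(dim = d, acc = m$acc, macro_f1 = m$macro_f1,
               macro_precision = m$macro_precision,
               macro_recall = m$macro_recall, seed = seed)
  })
  do.call(rbind, rows)
}
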