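#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure of a syndrome-centred
#' clinical corpus and knowledge graph: a set of syndrome classes, each with
#' its own symptom profile, cross-syndrome symptom overlap, synonym surface
#' variation, optional noise tokens, and (optionally) a geometric class-size
#' profile emulating extreme imbalance (a real corpus of this kind can have
#' a largest class of several thousand records and a smallest of a few
#' dozen). It does not attempt to mimic real clinical language — only the
#' overlap/imbalance/synonymy structure the pipeline must cope with.
#'
#' @param n_syndromes number of syndrome classes `S` (>= 2).
#' @param symptoms_per_syndrome symptoms in each syndrome's profile.
#' @param symptom_overlap_rate share of a syndrome's symptoms shared with
#'   the previous syndrome, in `[0, 1]`.
#' @param synonym_rate probability a rendered mention uses a synonym surface
#'   form instead of the canonical name, in `[0, 1]`.
#' @param n_synonyms_per_symptom synonym surface forms generated per symptom
#'   (they always enter the dictionary; `synonym_rate` governs usage).
#' @param records_per_class records per class when no imbalance profile is
#'   given.
#' @param imbalance optional `list(largest =, ratio =)`: class `j` gets
#'   `max(1, round(largest * ratio^(j-1)))` records.
#' @param noise_token_rate probability of injecting a noise token per
#'   history slot.
#' @param seed mandatory RNG seed.
#' @return a `synth_config`.
#' @export
synth_config <- function(n_syndromes = 5L, symptoms_per_syndrome = 4L,
                         symptom_overlap_rate = 0, synonym_rate = 0,
                         n_synonyms_per_symptom = 2L,
                         records_per_class = 30L, imbalance = NULL,
                         noise_token_rate = 0, seed) {
  if (missing(seed)) stopf("value error: seed is mandatory")
  if (n_syndromes < 2) stopf("value error: need at least 2 syndromes")
  rates <- c(symptom_overlap_rate, synonym_rate, noise_token_rate)
  if (any(rates < 0 | rates > 1)) stopf("value error: rates must be in [0,1]")
  structure(list(n_syndromes = as.integer(n_syndromes),
                 symptoms_per_syndrome = as.integer(symptoms_per_syndrome),
                 symptom_overlap_rate = symptom_overlap_rate,
                 synonym_rate = synonym_rate,
                 n_synonyms_per_symptom = as.integer(n_synonyms_per_symptom),
                 records_per_class = as.integer(records_per_class),
                 imbalance = imbalance,
                 noise_token_rate = noise_token_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

symptom_qualities <- c("aching", "burning", "dull", "sharp", "cold",
                       "damp", "heavy", "restless", "bitter", "pale")

#' Generate a syndrome-centred knowledge graph with dictionaries
#'
#' Builds `S` Syndrome nodes with full attribute sets, per-syndrome symptom
#' profiles (adjacent syndromes share `symptom_overlap_rate` of their
#' symptoms), and Treatment/Drugs/Flavor/Form and Disease chains following
#' the schema's relation signatures (two adjacent syndromes share one
#' disease, so the disease name alone is ambiguous). Symptom synonyms are
#' emitted into a symptom dictionary; gazetteer rows cover canonical names,
#' synonyms and syndrome names. Deterministic under the config seed.
#'
#' @param cfg a [synth_config()].
#' @return list with `kg`, `symptom_dict`, `syndrome_dict`, `gazetteer`,
#'   `profiles` (list of per-syndrome canonical symptom names) and
#'   `syndromes` (class id -> syndrome name).
#' @export
generate_kg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  S <- cfg$n_syndromes; k <- cfg$symptoms_per_syndrome
  with_seed(cfg$seed, {
    n_shared <- if (cfg$symptom_overlap_rate >= 1) k
                else round(cfg$symptom_overlap_rate * k)
    profiles <- vector("list", S)
    pool <- character(); counter <- 0L
    new_symptom <- function() {
      counter <<- counter + 1L
      paste(symptom_qualities[(counter - 1L) %% length(symptom_qualities) + 1L],
            sprintf("sx%02d", counter))
    }
    for (j in seq_len(S)) {
      if (j == 1L || n_shared == 0L) shared <- character()
      else if (n_shared >= k) { profiles[[j]] <- profiles[[1]]; next }
      else shared <- utils::tail(profiles[[j - 1L]], n_shared)
      fresh <- vapply(seq_len(k - length(shared)),
                      function(i) new_symptom(), "")
      profiles[[j]] <- c(shared, fresh)
      pool <- unique(c(pool, profiles[[j]]))
    }
    if (n_shared >= k) pool <- unique(unlist(profiles))
    syndromes <- sprintf("pattern p%02d syndrome", seq_len(S))
    kg <- kg_new(default_schema())
    res <- kg_add_nodes(kg, "Syndrome", syndromes, lapply(seq_len(S), function(j)
      c(Syndrome_name = syndromes[j],
        Syndrome_English = sprintf("pattern %d", j),
        Syndrome_PinYin = sprintf("zheng%02d", j),
        Syndrome_definition = paste("pattern marked by",
                                    paste(profiles[[j]], collapse = ", ")))))
    kg <- res$kg; syn_ids <- res$ids
    res <- kg_add_nodes(kg, "Symptoms", pool, lapply(pool, function(s)
      c(TCM_symptom_name = s,
        Symptom_PinYin = gsub(" ", "", s),
        Symptom_definition = paste("presentation of", s),
        Symptom_locus = "general", Symptom_property = "deficiency")))
    kg <- res$kg; sym_ids <- stats::setNames(res$ids, pool)
    for (j in seq_len(S))
      kg <- kg_add_triples(kg, rep(syn_ids[j], k), "Has_symptom",
                           sym_ids[profiles[[j]]])
    # treatment -> drugs -> flavor/form chains, one per syndrome
    treatments <- sprintf("method t%02d", seq_len(S))
    res <- kg_add_nodes(kg, "Treatment", treatments,
                        lapply(treatments, function(t) c(Treatment_name = t)))
    kg <- res$kg; tr_ids <- res$ids
    drugs <- sprintf("formula d%02d", seq_len(S))
    res <- kg_add_nodes(kg, "Drugs", drugs,
                        lapply(drugs, function(d) c(Drugs_name = d)))
    kg <- res$kg; dr_ids <- res$ids
    flavors <- c("sweet", "bitter flavor", "pungent")
    res <- kg_add_nodes(kg, "Flavor", flavors,
                        lapply(flavors, function(f) c(Flavor_name = f)))
    kg <- res$kg; fl_ids <- res$ids
    forms <- c("decoction", "pill")
    res <- kg_add_nodes(kg, "Form", forms,
                        lapply(forms, function(f) c(Form_name = f)))
    kg <- res$kg; fo_ids <- res$ids
    diseases <- sprintf("disorder z%02d", seq_len(ceiling(S / 2)))
    res <- kg_add_nodes(kg, "Disease", diseases,
                        lapply(diseases, function(d) c(Disease_name = d)))
    kg <- res$kg; di_ids <- res$ids
    kg <- kg_add_triples(kg, syn_ids, "Has_treatment", tr_ids)
    kg <- kg_add_triples(kg, tr_ids, "Common pharmaceuticals", dr_ids)
    kg <- kg_add_triples(kg, dr_ids, "Has_flavor",
                         fl_ids[(seq_len(S) - 1L) %% length(fl_ids) + 1L])
    kg <- kg_add_triples(kg, dr_ids, "Dosage form",
                         fo_ids[(seq_len(S) - 1L) %% length(fo_ids) + 1L])
    kg <- kg_add_triples(kg, syn_ids, "Has_disease",
                         di_ids[ceiling(seq_len(S) / 2)])
    # synonym dictionary
    syn_df <- data.frame(surface = character(), canonical = character())
    if (cfg$n_synonyms_per_symptom > 0) {
      # synonym surfaces are single fused tokens: lexically close to the
      # canonical name (character n-grams) but sharing no word token with
      # it, so surface variation is opaque to a word-level text encoder
      # while the semantic fallback can still resolve it
      for (s in pool)
        for (v in seq_len(cfg$n_synonyms_per_symptom))
          syn_df <- rbind(syn_df, data.frame(
            surface = sprintf("%sv%d", gsub(" ", "", s), v), canonical = s))
    }
    symptom_dict <- term_dictionary(pool, syn_df, "symptom")
    syndrome_dict <- term_dictionary(syndromes, domain = "syndrome")
    gazetteer <- rbind(
      data.frame(term = pool, type = "Symptoms"),
      if (nrow(syn_df)) data.frame(term = syn_df$surface, type = "Symptoms"),
      data.frame(term = syndromes, type = "Syndrome"))
    list(kg = kg, symptom_dict = symptom_dict, syndrome_dict = syndrome_dict,
         gazetteer = gazetteer, profiles = profiles,
         syndromes = syndromes, disease_of = diseases[ceiling(seq_len(S) / 2)])
  })
}

render_mention <- function(canonical, dict, synonym_rate) {
  syn <- dict$synonyms$surface[dict$synonyms$canonical == canonical]
  if (length(syn) && stats::runif(1) < synonym_rate)
    syn[sample.int(length(syn), 1L)]
  else canonical
}

#' Generate an EMR corpus from a synthetic knowledge graph
#'
#' Each record samples a subset of its syndrome's symptom profile, renders
#' the mentions as canonical names or synonyms (at `synonym_rate`), joins
#' part of them with conjunctions/commas in the chief complaint (exercising
#' composite-label splitting), puts the rest plus optional noise tokens into
#' the history, and labels the record with the generating class. Class
#' sizes follow `records_per_class` or the geometric imbalance profile.
#'
#' @param bundle output of [generate_kg()].
#' @param cfg the same [synth_config()].
#' @return list with `records` (list of [emr_record()]s), `mentions`
#'   (character vectors of the raw rendered mentions per record) and
#'   `class_sizes`.
#' @export
generate_emrs <- function(bundle, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  S <- cfg$n_syndromes
  if (!nrow(bundle$kg$nodes)) stopf("value error: empty knowledge graph")
  sizes <- if (is.null(cfg$imbalance)) rep(cfg$records_per_class, S)
    else vapply(seq_len(S), function(j)
      max(1L, as.integer(round(cfg$imbalance$largest *
                                 cfg$imbalance$ratio^(j - 1L)))), 0L)
  with_seed(cfg$seed + 1L, {
    records <- list(); mentions <- list()
    for (j in seq_len(S)) {
      prof <- bundle$profiles[[j]]
      for (r in seq_len(sizes[j])) {
        n_m <- sample(2:max(2L, length(prof)), 1L)
        can <- sample(prof, min(n_m, length(prof)))
        surf <- vapply(can, render_mention, "", dict = bundle$symptom_dict,
                       synonym_rate = cfg$synonym_rate)
        n_c <- ceiling(length(surf) / 2)
        joiner <- sample(c(" and ", ", ", " with "), 1L)
        complaint <- paste(surf[seq_len(n_c)], collapse = joiner)
        hist_parts <- surf[-seq_len(n_c)]
        if (cfg$noise_token_rate > 0) {
          n_noise <- stats::rbinom(1L, 3L, cfg$noise_token_rate)
          if (n_noise > 0)
            hist_parts <- c(hist_parts,
                            sprintf("note n%03d", sample.int(500L, n_noise)))
        }
        history <- if (length(hist_parts))
          paste(hist_parts, collapse = ", ") else ""
        records[[length(records) + 1L]] <- emr_record(
          disease_name = bundle$disease_of[j],
          chief_complaint = complaint, history = history,
          label = j - 1L)
        mentions[[length(mentions) + 1L]] <- unname(surf)
      }
    }
    list(records = records, mentions = mentions, class_sizes = sizes)
  })
}

complaint_pool <- sprintf("persistent discomfort c%02d", 1:6)

#' Generate a BIO-annotated tagging corpus
#'
#' Emits word-token sentences mentioning symptom, disease, syndrome and
#' chief-complaint entities from the synthetic graph with guaranteed
#' well-formed BIO tags (types SYMPTOM, DISEASE, SYNDROME, COMPLAINT).
#'
#' @param bundle output of [generate_kg()].
#' @param cfg a [synth_config()].
#' @param n_sentences number of sentences.
#' @return list of [tagged_sequence()]s.
#' @export
generate_tagging_corpus <- function(bundle, cfg, n_sentences = 200L) {
  with_seed(cfg$seed + 2L, {
    S <- cfg$n_syndromes
    out <- vector("list", n_sentences)
    add_entity <- function(toks, tags, phrase, type) {
      words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
      list(c(toks, words),
           c(tags, paste0("B-", type),
             rep(paste0("I-", type), length(words) - 1L)))
    }
    for (i in seq_len(n_sentences)) {
      j <- sample.int(S, 1L)
      prof <- bundle$profiles[[j]]
      toks <- c("patient", "reports"); tags <- c("O", "O")
      if (stats::runif(1) < 0.4) {
        z <- add_entity(toks, tags,
                        complaint_pool[sample.int(length(complaint_pool), 1L)],
                        "COMPLAINT")
        toks <- z[[1]]; tags <- c(z[[2]])
        toks <- c(toks, "and"); tags <- c(tags, "O")
      }
      n_sym <- sample(1:2, 1L)
      for (s in sample(prof, n_sym)) {
        z <- add_entity(toks, tags, s, "SYMPTOM")
        toks <- z[[1]]; tags <- z[[2]]
        toks <- c(toks, "and"); tags <- c(tags, "O")
      }
      toks[length(toks)] <- "from"          # replace trailing "and"
      z <- add_entity(toks, tags, bundle$disease_of[j], "DISEASE")
      toks <- z[[1]]; tags <- z[[2]]
      toks <- c(toks, "diagnosed", "as"); tags <- c(tags, "O", "O")
      z <- add_entity(toks, tags, bundle$syndromes[j], "SYNDROME")
      out[[i]] <- tagged_sequence(z[[1]], z[[2]])
    }
    out
  })
}

#' Scenario presets backing the evaluation harnesses
#'
#' \describe{
#'   \item{clean}{no synonyms, no noise, disjoint symptom profiles; every
#'     mention exact-matches a graph node.}
#'   \item{synonym-heavy}{most mentions are synonym surface forms, so exact
#'     matching fails often and the semantic fallback carries the signal.}
#'   \item{complementary-signal}{overlapping symptom profiles plus heavy
#'     synonym variation and noise: the raw text is ambiguous, canonicalized
#'     knowledge links disambiguate.}
#'   \item{text-sufficient}{clean regime where the text alone determines the
#'     label.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return list with `cfg`, the [generate_kg()] bundle and the
#'   [generate_emrs()] corpus.
#' @export
scenario_preset <- function(name = c("clean", "synonym-heavy",
                                     "complementary-signal",
                                     "text-sufficient"),
                            seed = 7L) {
  name <- match.arg(name)
  cfg <- switch(name,
    "clean" = ,
    "text-sufficient" = synth_config(
      n_syndromes = 4L, symptoms_per_syndrome = 4L,
      symptom_overlap_rate = 0, synonym_rate = 0, noise_token_rate = 0,
      records_per_class = 30L, seed = seed),
    "synonym-heavy" = synth_config(
      n_syndromes = 4L, symptoms_per_syndrome = 4L,
      symptom_overlap_rate = 0.25, synonym_rate = 0.9,
      n_synonyms_per_symptom = 8L, noise_token_rate = 0.1,
      records_per_class = 30L, seed = seed),
    "complementary-signal" = synth_config(
      n_syndromes = 4L, symptoms_per_syndrome = 4L,
      symptom_overlap_rate = 0.75, synonym_rate = 0.9,
      n_synonyms_per_symptom = 12L, noise_token_rate = 0.3,
      records_per_class = 60L, seed = seed))
  bundle <- generate_kg(cfg)
  corpus <- generate_emrs(bundle, cfg)
  list(name = name, cfg = cfg, bundle = bundle, corpus = corpus)
}
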