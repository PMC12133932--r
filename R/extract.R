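#' Entity extraction backends
#'
#' Extraction of symptom/syndrome entities and their relations from
#' semi-structured text is abstracted behind a backend contract: a backend
#' is a list with a `name` and an `extract(text)` function returning an
#' `extraction_result`. The package ships a deterministic gazetteer backend
#' ([rule_backend()]); a hosted-LLM backend can be plugged in behind the same
#' contract (see [llm_backend_stub()]).
#'
#' An `extraction_result` holds the symptom entities `E_Sz`, syndrome
#' entities `E_Sh`, relations, and triples `(E_Sz, relation, E_Sh)`; its
#' relation names must belong to the schema's relation set and every triple
#' endpoint must appear in the entity lists.
#'
#' @param symptoms,syndromes character vectors of extracted surface forms.
#' @param triples data.frame with columns `symptom`, `relation`, `syndrome`.
#' @param schema a [kg_schema] used to validate relation names.
#' @return an `extraction_result`.
#' @export
extraction_result <- function(symptoms = character(), syndromes = character(),
                              triples = data.frame(symptom = character(),
                                                   relation = character(),
                                                   syndrome = character()),
                              schema = default_schema()) {
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  if (nrow(triples)) {
    bad <- setdiff(triples$relation, schema$relations$relation)
    if (length(bad))
      stopf("schema error: relation '%s' outside the schema", bad[1])
    if (!all(triples$symptom %in% symptoms) ||
        !all(triples$syndrome %in% syndromes))
      stopf("extraction error: triple endpoint missing from entity lists")
  }
  structure(list(symptoms = symptoms, syndromes = syndromes,
                 triples = triples),
            class = "extraction_result")
}

#' Deterministic gazetteer extraction backend
#'
#' Matches gazetteer terms in the text with leftmost-longest Aho-Corasick
#' matching and emits one `(symptom, Has_symptom, syndrome)` triple per
#' symptom/syndrome pair co-occurring in the text. A pure function of
#' `(text, gazetteer)`; output order is deterministic (text order for
#' entities, sorted pairs for triples).
#'
#' @param gazetteer data.frame with columns `term`, `type` (`"Symptoms"` or
#'   `"Syndrome"`).
#' @param schema a [kg_schema].
#' @return a backend usable with [extract_entities()].
#' @export
rule_backend <- function(gazetteer, schema = default_schema()) {
  gazetteer <- as.data.frame(gazetteer, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "type") %in% names(gazetteer)))
  gazetteer <- unique(gazetteer[, c("term", "type")])
  ac <- ac_automaton(gazetteer$term)
  list(
    name = "rules",
    extract = function(text) {
      hits <- select_leftmost_longest(ac_find(ac, text))
      terms <- gazetteer$term[hits$pattern]
      types <- gazetteer$type[hits$pattern]
      sym <- unique(terms[types == "Symptoms"])
      syn <- unique(terms[types == "Syndrome"])
      tri <- if (length(sym) && length(syn))
        expand.grid(symptom = sort(sym), syndrome = sort(syn),
                    stringsAsFactors = FALSE)
      else data.frame(symptom = character(), syndrome = character())
      tri$relation <- rep("Has_symptom", nrow(tri))
      extraction_result(sym, syn,
                        tri[, c("symptom", "relation", "syndrome")], schema)
    })
}

#' Adapter stub for a hosted-LLM extraction backend
#'
#' Documents the prompt contract a large-language-model backend would use:
#' the input text is wrapped in an instruction that names the target entity
#' categories (symptom, syndrome) and asks for entity lists plus
#' `(symptom, relation, syndrome)` triples in JSON. The stub performs no
#' network call: `extract()` raises an extraction error unless a `responder`
#' function (e.g. a recorded-response player for tests) is supplied.
#'
#' @param responder optional function `text -> extraction_result` standing in
#'   for the remote model.
#' @return a backend with the same contract as [rule_backend()].
#' @export
llm_backend_stub <- function(responder = NULL) {
  prompt_template <- paste(
    "Extract the entities of categories [symptom, syndrome] from the",
    "following clinical text, and list every (symptom, relation, syndrome)",
    "pair you can justify. Respond in JSON with fields symptoms, syndromes,",
    "triples. Text: {text}")
  list(
    name = "llm-stub",
    prompt_template = prompt_template,
    extract = function(text) {
      if (is.null(responder))
        stopf("extraction error: llm backend has no responder configured")
      responder(text)
    })
}

#' Extract entities from a text with a backend
#'
#' Validates the backend's output (entity/triple consistency, relation names
#' inside the schema). Backend failures are re-raised as extraction errors
#' carrying the backend diagnostics; an error is never silently turned into
#' an empty result.
#'
#' @param text non-empty string.
#' @param backend a backend (see [rule_backend()]).
#' @param schema a [kg_schema].
#' @return an `extraction_result`.
#' @export
extract_entities <- function(text, backend, schema = default_schema()) {
  if (!nzchar(text)) stopf("value error: empty text")
  res <- tryCatch(backend$extract(text), error = function(e)
    stopf("extraction error in backend '%s': %s",
          backend$name %||% "?", conditionMessage(e)))
  if (!inherits(res, "extraction_result"))
    res <- extraction_result(res$symptoms, res$syndromes, res$triples, schema)
  res
}

#' Convert an extraction result to schema-oriented graph triples
#'
#' Extraction emits `(symptom, Has_symptom, syndrome)`; the schema stores
#' `(Syndrome, Has_symptom, Symptoms)`, so endpoints are flipped here.
#'
#' @param res an `extraction_result`.
#' @return data.frame with columns `head`, `relation`, `tail` of node
#'   canonical names (head = syndrome).
#' @export
extraction_to_triples <- function(res) {
  data.frame(head = res$triples$syndrome,
             relation = res$triples$relation,
             tail = res$triples$symptom,
             stringsAsFactors = FALSE)
}
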