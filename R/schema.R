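#' Entity/relation schema for a syndrome-centred knowledge graph
#'
#' A `kg_schema` declares the permitted entity types, the ordered attribute
#' names each type may carry, and the typed relation signatures
#' `(head_type, relation, tail_type)` that triples must conform to.
#'
#' The default schema (see [default_schema()]) describes a TCM knowledge
#' graph centred on syndromes: core entities (Syndrome, Symptoms, Herb) carry
#' rich attribute sets (names, PinYin transliterations, definitions,
#' properties), and nine relation signatures connect syndromes to diseases,
#' symptoms and treatments, treatments to drugs, drugs to flavors/forms/
#' formula groups, and diseases to patient and disease groups.
#'
#' @param entity_types character vector of declared type names.
#' @param attributes named list, one character vector of attribute names per
#'   entity type. Every list must be non-empty and duplicate-free.
#' @param relations data.frame with columns `head_type`, `relation`,
#'   `tail_type`; every endpoint must be a declared entity type.
#' @return an object of class `kg_schema`.
#' @export
kg_schema <- function(entity_types, attributes, relations) {
  if (anyDuplicated(entity_types))
    stopf("schema error: duplicate entity type '%s'",
          entity_types[duplicated(entity_types)][1])
  if (!all(names(attributes) %in% entity_types))
    stopf("schema error: attributes declared for unknown type '%s'",
          setdiff(names(attributes), entity_types)[1])
  for (ty in names(attributes)) {
    a <- attributes[[ty]]
    if (length(a) == 0) stopf("schema error: empty attribute list for '%s'", ty)
    if (anyDuplicated(a)) stopf("schema error: duplicate attribute for '%s'", ty)
  }
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  need <- c("head_type", "relation", "tail_type")
  if (!all(need %in% names(relations)))
    stopf("schema error: relations need columns %s", paste(need, collapse = ", "))
  bad <- setdiff(c(relations$head_type, relations$tail_type), entity_types)
  if (length(bad))
    stopf("schema error: relation references unknown entity type '%s'", bad[1])
  structure(list(entity_types = entity_types,
                 attributes = attributes,
                 relations = relations[, need]),
            class = "kg_schema")
}

#' Built-in syndrome-centred schema
#'
#' Eleven entity types; the three core types carry their canonical attribute
#' lists (Syndrome: 4 attributes, Symptoms: 5, Herb: 5), secondary types carry
#' a single `<Type>_name` attribute; exactly nine relation signatures.
#'
#' @return a `kg_schema`.
#' @export
default_schema <- function() {
  core <- list(
    Syndrome = c("Syndrome_name", "Syndrome_English", "Syndrome_PinYin",
                 "Syndrome_definition"),
    Symptoms = c("TCM_symptom_name", "Symptom_PinYin", "Symptom_definition",
                 "Symptom_locus", "Symptom_property"),
    Herb = c("Chinese_name", "Pinyin_name", "English_name",
             "Properties_Chinese", "Meridians_Chinese"))
  secondary <- c("Treatment", "Disease", "Drugs", "Flavor", "Form",
                 "Patients", "Dgroup", "Fgroup")
  attributes <- c(core, stats::setNames(
    lapply(secondary, function(t) paste0(t, "_name")), secondary))
  relations <- data.frame(
    head_type = c("Syndrome", "Syndrome", "Syndrome", "Treatment", "Drugs",
                  "Drugs", "Disease", "Disease", "Drugs"),
    relation  = c("Has_disease", "Has_symptom", "Has_treatment",
                  "Common pharmaceuticals", "Has_flavor", "Dosage form",
                  "Common patients", "IspartofD", "IspartofP"),
    tail_type = c("Disease", "Symptoms", "Treatment", "Drugs", "Flavor",
                  "Form", "Patients", "Dgroup", "Fgroup"),
    stringsAsFactors = FALSE)
  kg_schema(c(names(core), secondary), attributes, relations)
}

#' Load a schema from a JSON document
#'
#' The document has the shape
#' `{"entity_types": {"Type": ["attr", ...], ...},
#'   "relations": [{"head_type":..., "relation":..., "tail_type":...}, ...]}`.
#' With `source = NULL` the built-in schema is returned.
#'
#' @param source path to a JSON schema file, or `NULL` for the default.
#' @return a `kg_schema`.
#' @export
load_schema <- function(source = NULL) {
  if (is.null(source)) return(default_schema())
  doc <- jsonlite::fromJSON(source, simplifyDataFrame = TRUE)
  if (is.null(doc$entity_types) || is.null(doc$relations))
    stopf("schema error: document must contain entity_types and relations")
  ets <- names(doc$entity_types)
  attributes <- lapply(doc$entity_types, as.character)
  kg_schema(ets, attributes, as.data.frame(doc$relations))
}

#' @export
print.kg_schema <- function(x, ...) {
  cat(sprintf("<kg_schema: %d entity types, %d relation signatures>\n",
              length(x$entity_types), nrow(x$relations)))
  invisible(x)
}

# TRUE iff (head_type, relation, tail_type) is a declared signature.
schema_allows <- function(schema, head_type, relation, tail_type) {
  r <- schema$relations
  any(r$head_type == head_type & r$relation == relation &
        r$tail_type == tail_type)
}

# Infer endpoint types from a relation name; relation names in the default
# schema are unique, so this is well-defined there.
schema_relation_types <- function(schema, relation) {
  r <- schema$relations[schema$relations$relation == relation, ]
  if (nrow(r) == 0) return(NULL)
  list(head_type = r$head_type[1], tail_type = r$tail_type[1])
}

schemas_identical <- function(a, b) {
  identical(a$entity_types, b$entity_types) &&
    identical(a$attributes, b$attributes) &&
    identical(a$relations, b$relations)
}
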