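#' Term dictionaries for vocabulary normalization
#'
#' A `term_dictionary` holds the canonical vocabulary for one domain
#' (symptom or syndrome) plus a synonym map from surface forms to canonical
#' terms. Every synonym must map to a declared canonical term and no surface
#' form may map to two canonicals.
#'
#' @param canonical_terms character vector of canonical terms.
#' @param synonyms data.frame with columns `surface`, `canonical` (may be
#'   empty).
#' @param domain `"symptom"` or `"syndrome"`.
#' @return a `term_dictionary`.
#' @export
term_dictionary <- function(canonical_terms,
                            synonyms = data.frame(surface = character(),
                                                  canonical = character()),
                            domain = c("symptom", "syndrome")) {
  domain <- match.arg(domain)
  canonical_terms <- unique(as.character(canonical_terms))
  synonyms <- as.data.frame(synonyms, stringsAsFactors = FALSE)
  if (nrow(synonyms)) {
    if (anyDuplicated(synonyms$surface))
      stopf("dictionary error: surface form maps to two canonicals")
    bad <- setdiff(synonyms$canonical, canonical_terms)
    if (length(bad))
      stopf("dictionary error: synonym target '%s' is not canonical", bad[1])
  }
  structure(list(canonical_terms = canonical_terms, synonyms = synonyms,
                 domain = domain),
            class = "term_dictionary")
}

#' Read a dictionary from CSV (columns surface, canonical, domain)
#'
#' Rows where `surface == canonical` declare canonical terms; all canonicals
#' referenced by synonyms are added to the canonical set.
#' @param path CSV path.
#' @param domain dictionary domain to keep.
#' @return a `term_dictionary`.
#' @export
read_dictionary_csv <- function(path, domain = c("symptom", "syndrome")) {
  domain <- match.arg(domain)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$domain == domain, , drop = FALSE]
  canon <- unique(df$canonical)
  syn <- df[df$surface != df$canonical, c("surface", "canonical")]
  term_dictionary(canon, syn, domain)
}

# ---------------------------------------------------------------------------
# Aho-Corasick automaton (trie + failure links), character-level, UTF-8.
# Built from scratch because exact multi-pattern matching with
# leftmost-longest semantics is a core primitive of the cleaning pipeline.

#' Build an Aho-Corasick automaton over a pattern set
#'
#' @param patterns non-empty character vector of non-empty patterns.
#' @return an `ac_automaton` usable with [ac_find()].
#' @export
ac_automaton <- function(patterns) {
  patterns <- as.character(patterns)
  if (!length(patterns) || any(!nzchar(patterns)))
    stopf("configuration error: automaton needs non-empty patterns")
  children <- list(character())          # node -> named vector char -> child
  fail <- 1L
  out <- list(integer())                 # node -> pattern indices ending here
  new_node <- function() {
    children[[length(children) + 1L]] <<- character()
    out[[length(out) + 1L]] <<- integer()
    length(children)
  }
  for (p in seq_along(patterns)) {
    chars <- strsplit(patterns[p], "", fixed = TRUE)[[1]]
    node <- 1L
    for (ch in chars) {
      nxt <- children[[node]][ch]
      if (is.na(nxt)) {
        id <- new_node()
        children[[node]][ch] <- id
        node <- id
      } else node <- as.integer(nxt)
    }
    out[[node]] <- c(out[[node]], p)
  }
  # BFS failure links; merge outputs through failures
  fail <- rep(1L, length(children))
  queue <- as.integer(children[[1]])
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    for (ch in names(children[[node]])) {
      child <- as.integer(children[[node]][ch])
      f <- fail[node]
      while (f != 1L && is.na(children[[f]][ch])) f <- fail[f]
      cand <- children[[f]][ch]
      fail[child] <- if (!is.na(cand) && as.integer(cand) != child)
        as.integer(cand) else 1L
      out[[child]] <- c(out[[child]], out[[fail[child]]])
      queue <- c(queue, child)
    }
  }
  structure(list(patterns = patterns, children = children, fail = fail,
                 out = out),
            class = "ac_automaton")
}

#' Find all pattern occurrences in a text
#'
#' @param ac an [ac_automaton()].
#' @param text a string.
#' @return data.frame with columns `pattern` (index into the automaton's
#'   pattern vector), `start`, `end` (1-based inclusive character positions),
#'   listing every occurrence.
#' @export
ac_find <- function(ac, text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  node <- 1L
  hit_p <- integer(); hit_e <- integer()
  for (i in seq_along(chars)) {
    ch <- chars[i]
    repeat {
      nxt <- ac$children[[node]][ch]
      if (!is.na(nxt)) { node <- as.integer(nxt); break }
      if (node == 1L) break
      node <- ac$fail[node]
    }
    if (length(ac$out[[node]])) {
      hit_p <- c(hit_p, ac$out[[node]])
      hit_e <- c(hit_e, rep(i, length(ac$out[[node]])))
    }
  }
  lens <- nchar(ac$patterns)[hit_p]
  data.frame(pattern = hit_p, start = hit_e - lens + 1L, end = hit_e)
}

# Greedy leftmost-longest selection over candidate spans (1-based inclusive).
select_leftmost_longest <- function(cand) {
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
  keep <- integer(); last_end <- 0L
  for (r in seq_len(nrow(cand))) {
    if (cand$start[r] > last_end) {
      keep <- c(keep, r)
      last_end <- cand$end[r]
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate symptom spans in free text with a regex set
#'
#' All matches of all patterns are collected; overlaps are resolved longest
#' match first (ties: leftmost), and the surviving spans are returned sorted
#' and non-overlapping as 0-based half-open `[start, end)` intervals.
#'
#' @param text a string.
#' @param patterns character vector of regular expressions.
#' @return data.frame with integer columns `start`, `end` (0-based,
#'   half-open).
#' @export
locate_symptom_spans <- function(text, patterns) {
  cand <- data.frame(start = integer(), end = integer())
  for (p in patterns) {
    m <- tryCatch(
      withCallingHandlers(gregexpr(p, text, perl = TRUE)[[1]],
                          warning = function(w) stop(conditionMessage(w))),
      error = function(e)
        stopf("configuration error: bad pattern '%s': %s",
              p, conditionMessage(e)))
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    cand <- rbind(cand, data.frame(start = as.integer(m),
                                   end = as.integer(m) + len - 1L))
  }
  if (!nrow(cand)) return(data.frame(start = integer(), end = integer()))
  # longest-first greedy, then report sorted
  cand <- unique(cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  keep <- data.frame(start = integer(), end = integer())
  for (r in seq_len(nrow(cand))) {
    if (!any(cand$start[r] <= keep$end & cand$end[r] >= keep$start))
      keep <- rbind(keep, cand[r, ])
  }
  keep <- keep[order(keep$start), , drop = FALSE]
  rownames(keep) <- NULL
  data.frame(start = keep$start - 1L, end = keep$end)  # 0-based half-open
}

#' Default connective configuration for composite-label splitting
#'
#' Conjunction/disjunction connectives used to split composite symptom or
#' syndrome labels into atomic ones: the English words and/or/with,
#' enumeration commas, and the Chinese connectives
#' \code{"和"}, \code{"及"}, \code{"并"}, \code{"伴"} and the
#' enumeration comma \code{"、"}.
#' @export
default_connectives <- function() {
  list(words = c("and", "or", "with"),
       chars = c("和", "及", "并", "伴"),
       separators = c(",", ";", "、", "，", "；"))
}

#' Split a composite label into atomic labels
#'
#' @param label non-empty string.
#' @param connectives configuration as produced by [default_connectives()].
#' @return character vector of trimmed, non-empty atoms in input order.
#' @export
split_composite_label <- function(label, connectives = default_connectives()) {
  if (!nzchar(trimws(label)))
    stopf("value error: empty label")
  esc <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
  parts <- c(
    if (length(connectives$separators))
      paste0("[", paste(esc(connectives$separators), collapse = ""), "]"),
    if (length(connectives$words))
      paste0("\\b(?:", paste(connectives$words, collapse = "|"), ")\\b"),
    if (length(connectives$chars))
      paste0("[", paste(connectives$chars, collapse = ""), "]"))
  rx <- paste0("\\s*(?:", paste(parts, collapse = "|"), ")\\s*")
  atoms <- strsplit(label, rx, perl = TRUE)[[1]]
  atoms <- trimws(atoms)
  atoms[nzchar(atoms)]
}

#' Normalize a term against a dictionary
#'
#' Builds an Aho-Corasick automaton over canonical terms and synonym surface
#' forms and rewrites the input with leftmost-longest matching: each matched
#' surface form is replaced by its canonical term (canonical terms map to
#' themselves). Unmatched input is returned unchanged with `matched = FALSE`.
#'
#' @param term input string.
#' @param dict a [term_dictionary()].
#' @return a `normalization_report`: list with `input_term`, `output_terms`
#'   (length-1 character), `matched` (logical per output), `rule_trace`
#'   (character vector of applied rewrites).
#' @export
normalize_term <- function(term, dict) {
  stopifnot(inherits(dict, "term_dictionary"))
  surfaces <- c(dict$canonical_terms, dict$synonyms$surface)
  if (!length(surfaces))
    stopf("configuration error: empty dictionary")
  targets <- c(dict$canonical_terms, dict$synonyms$canonical)
  if (!nzchar(term))
    return(structure(list(input_term = term, output_terms = character(),
                          matched = logical(), rule_trace = character()),
                     class = "normalization_report"))
  ac <- attr(dict, "automaton")
  if (is.null(ac)) ac <- ac_automaton(surfaces)
  hits <- select_leftmost_longest(ac_find(ac, term))
  chars <- strsplit(term, "", fixed = TRUE)[[1]]
  if (!nrow(hits)) {
    return(structure(list(input_term = term, output_terms = term,
                          matched = FALSE, rule_trace = character()),
                     class = "normalization_report"))
  }
  out <- character(); pos <- 1L; trace <- character()
  for (r in seq_len(nrow(hits))) {
    if (hits$start[r] > pos)
      out <- c(out, paste(chars[pos:(hits$start[r] - 1L)], collapse = ""))
    surf <- surfaces[hits$pattern[r]]
    canon <- targets[hits$pattern[r]]
    out <- c(out, canon)
    if (surf != canon)
      trace <- c(trace, sprintf("ac:%s->%s@%d", surf, canon, hits$start[r]))
    else
      trace <- c(trace, sprintf("ac:%s@%d", canon, hits$start[r]))
    pos <- hits$end[r] + 1L
  }
  if (pos <= length(chars))
    out <- c(out, paste(chars[pos:length(chars)], collapse = ""))
  structure(list(input_term = term,
                 output_terms = paste(out, collapse = ""),
                 matched = TRUE, rule_trace = trace),
            class = "normalization_report")
}

# Precompile the automaton onto a dictionary (perf helper).
compile_dictionary <- function(dict) {
  surfaces <- c(dict$canonical_terms, dict$synonyms$surface)
  attr(dict, "automaton") <- ac_automaton(surfaces)
  dict
}

#' Merge duplicate nodes after normalization
#'
#' Canonical names of Symptoms and Syndrome nodes are rewritten through the
#' per-type dictionaries; nodes that then share `(entity_type,
#' canonical_name)` are merged into one node (attributes united keep-first),
#' and all triples are re-pointed and de-duplicated. Never increases node or
#' triple counts.
#'
#' @param kg a `knowledge_graph`.
#' @param dicts named list of [term_dictionary()]s keyed by entity type
#'   (e.g. `list(Symptoms = ..., Syndrome = ...)`).
#' @return the cleaned `knowledge_graph`.
#' @export
merge_duplicate_nodes <- function(kg, dicts) {
  stopifnot(inherits(kg, "knowledge_graph"))
  g <- kg
  for (ty in names(dicts)) {
    dic <- compile_dictionary(dicts[[ty]])
    rows <- which(g$nodes$type == ty)
    for (r in rows)
      g$nodes$name[r] <- normalize_term(g$nodes$name[r], dic)$output_terms
  }
  out <- kg_fuse(list(g))
  # merging same-type nodes cannot produce self-loops under the default
  # schema (all relations cross types), but guard anyway
  out$triples <- out$triples[out$triples$head != out$triples$tail, ,
                             drop = FALSE]
  rownames(out$triples) <- NULL
  out
}
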