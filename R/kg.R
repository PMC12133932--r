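#' Typed knowledge graph
#'
#' A `knowledge_graph` is a validated container of typed nodes and typed
#' triples under a [kg_schema]. Nodes carry a canonical name, a named
#' character vector of attributes (keys restricted to the schema's attribute
#' list for the node's type) and, after representation learning, an embedding
#' vector. Node ids are stable integers assigned at construction; all
#' iteration orders are sorted for reproducibility.
#'
#' @param schema a [kg_schema]; defaults to [default_schema()].
#' @return an empty `knowledge_graph`.
#' @export
kg_new <- function(schema = default_schema()) {
  structure(list(
    schema = schema,
    nodes = data.frame(id = integer(), type = character(),
                       name = character(), stringsAsFactors = FALSE),
    node_attrs = list(),     # named by id: named character vectors
    embeddings = list(),     # named by id: numeric vectors
    embedding_dim = NA_integer_,
    triples = data.frame(head = integer(), relation = character(),
                         tail = integer(), stringsAsFactors = FALSE)),
    class = "knowledge_graph")
}

#' Add nodes to a knowledge graph
#'
#' Existing `(type, name)` pairs are returned as-is (no duplicate is
#' created); attribute maps for existing nodes are merged keep-first.
#'
#' @param kg a `knowledge_graph`.
#' @param type entity type (scalar or vector recycled against `names`).
#' @param names canonical names.
#' @param attrs optional list of named character vectors, one per node.
#' @return list with elements `kg` (updated graph) and `ids` (integer ids in
#'   input order).
#' @export
kg_add_nodes <- function(kg, type, names, attrs = NULL) {
  stopifnot(inherits(kg, "knowledge_graph"))
  n <- length(names)
  type <- rep_len(type, n)
  bad <- setdiff(unique(type), kg$schema$entity_types)
  if (length(bad)) stopf("schema error: unknown entity type '%s'", bad[1])
  if (any(!nzchar(names))) stopf("node error: canonical_name must be non-empty")
  ids <- integer(n)
  next_id <- if (nrow(kg$nodes)) max(kg$nodes$id) + 1L else 1L
  for (i in seq_len(n)) {
    hit <- which(kg$nodes$type == type[i] & kg$nodes$name == names[i])
    if (length(hit)) {
      ids[i] <- kg$nodes$id[hit[1]]
    } else {
      ids[i] <- next_id
      kg$nodes <- rbind(kg$nodes, data.frame(
        id = next_id, type = type[i], name = names[i],
        stringsAsFactors = FALSE))
      next_id <- next_id + 1L
    }
    if (!is.null(attrs) && !is.null(attrs[[i]]) && length(attrs[[i]])) {
      a <- attrs[[i]]
      allowed <- kg$schema$attributes[[type[i]]]
      extra <- setdiff(names(a), allowed)
      if (length(extra))
        stopf("schema error: attribute '%s' not declared for type '%s'",
              extra[1], type[i])
      key <- as.character(ids[i])
      old <- kg$node_attrs[[key]]
      keep <- if (is.null(old)) a else c(old, a[setdiff(names(a), names(old))])
      kg$node_attrs[[key]] <- keep
    }
  }
  list(kg = kg, ids = ids)
}

#' Add triples to a knowledge graph
#'
#' Each triple's typed signature `(head_type, relation, tail_type)` must be a
#' declared schema signature; self-loops are rejected. Duplicate triples are
#' dropped.
#'
#' @param kg a `knowledge_graph`.
#' @param head,tail integer node ids.
#' @param relation relation names.
#' @return the updated graph.
#' @export
kg_add_triples <- function(kg, head, relation, tail) {
  stopifnot(inherits(kg, "knowledge_graph"))
  n <- length(head)
  relation <- rep_len(relation, n)
  idx <- match(head, kg$nodes$id)
  jdx <- match(tail, kg$nodes$id)
  if (anyNA(idx) || anyNA(jdx))
    stopf("triple error: endpoint id not present in graph")
  if (any(head == tail))
    stopf("triple error: self-loops are not allowed by the schema")
  for (i in seq_len(n)) {
    if (!schema_allows(kg$schema, kg$nodes$type[idx[i]], relation[i],
                       kg$nodes$type[jdx[i]]))
      stopf("schema error: signature (%s, %s, %s) not declared",
            kg$nodes$type[idx[i]], relation[i], kg$nodes$type[jdx[i]])
  }
  tr <- rbind(kg$triples, data.frame(head = as.integer(head),
                                     relation = relation,
                                     tail = as.integer(tail),
                                     stringsAsFactors = FALSE))
  kg$triples <- unique(tr)
  rownames(kg$triples) <- NULL
  kg
}

#' Validate a knowledge graph against its schema
#'
#' Checks triple endpoints exist, typed signatures are declared, attribute
#' keys are allowed, names are unique within type, and embedding lengths are
#' consistent.
#'
#' @param kg a `knowledge_graph`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
kg_validate <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (anyDuplicated(kg$nodes$id)) stopf("kg error: duplicate node id")
  if (anyDuplicated(paste0(kg$nodes$type, "\r", kg$nodes$name)))
    stopf("kg error: two nodes share (entity_type, canonical_name)")
  idx <- match(kg$triples$head, kg$nodes$id)
  jdx <- match(kg$triples$tail, kg$nodes$id)
  if (anyNA(idx) || anyNA(jdx)) stopf("kg error: dangling triple endpoint")
  for (i in seq_len(nrow(kg$triples))) {
    if (!schema_allows(kg$schema, kg$nodes$type[idx[i]],
                       kg$triples$relation[i], kg$nodes$type[jdx[i]]))
      stopf("schema error: signature (%s, %s, %s) not declared",
            kg$nodes$type[idx[i]], kg$triples$relation[i],
            kg$nodes$type[jdx[i]])
  }
  for (key in names(kg$node_attrs)) {
    row <- match(as.integer(key), kg$nodes$id)
    if (is.na(row)) stopf("kg error: attributes for unknown node %s", key)
    allowed <- kg$schema$attributes[[kg$nodes$type[row]]]
    extra <- setdiff(names(kg$node_attrs[[key]]), allowed)
    if (length(extra))
      stopf("schema error: attribute '%s' not declared for type '%s'",
            extra[1], kg$nodes$type[row])
  }
  dims <- unique(vapply(kg$embeddings, length, 1L))
  if (length(dims) > 1) stopf("kg error: inconsistent embedding dimensions")
  invisible(TRUE)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph: %d nodes, %d triples%s>\n",
              nrow(x$nodes), nrow(x$triples),
              if (length(x$embeddings))
                sprintf(", embeddings dim %d", x$embedding_dim) else ""))
  invisible(x)
}

# Canonical-name index: id of the node with (type, name), or NA.
kg_find_node <- function(kg, type, name) {
  hit <- which(kg$nodes$type == type & kg$nodes$name == name)
  if (length(hit)) kg$nodes$id[hit[1]] else NA_integer_
}

kg_node_name <- function(kg, id) kg$nodes$name[match(id, kg$nodes$id)]
kg_node_type <- function(kg, id) kg$nodes$type[match(id, kg$nodes$id)]
kg_node_attr <- function(kg, id, attr) {
  a <- kg$node_attrs[[as.character(id)]]
  if (is.null(a)) NA_character_ else unname(a[attr])
}

#' Fuse several knowledge graphs into one
#'
#' Multi-source graph fusion: nodes equal on `(entity_type, canonical_name)`
#' are merged into a single node (attribute maps united keep-first, first
#' occurrence in input order wins and conflicts are recorded), triples are
#' re-pointed to the merged ids and de-duplicated. Inputs are unmodified.
#' Node ids in the result are reassigned `1..n` in sorted `(type, name)`
#' order.
#'
#' @param graphs list of `knowledge_graph`s sharing one schema.
#' @return the merged `knowledge_graph`; discarded conflicting attribute
#'   values are attached as attribute `"conflicts"` (a data.frame).
#' @export
kg_fuse <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  for (g in graphs) stopifnot(inherits(g, "knowledge_graph"))
  sch <- graphs[[1]]$schema
  for (g in graphs[-1])
    if (!schemas_identical(sch, g$schema))
      stopf("fusion error: graphs do not share one schema")

  # collect nodes in input order for keep-first semantics
  keys <- character(); types <- character(); nms <- character()
  attr_acc <- list(); emb_acc <- list()
  conflicts <- list()
  for (g in graphs) {
    ord <- order(g$nodes$id)
    for (r in ord) {
      key <- paste0(g$nodes$type[r], "\r", g$nodes$name[r])
      pos <- match(key, keys)
      a <- g$node_attrs[[as.character(g$nodes$id[r])]]
      e <- g$embeddings[[as.character(g$nodes$id[r])]]
      if (is.na(pos)) {
        keys <- c(keys, key); types <- c(types, g$nodes$type[r])
        nms <- c(nms, g$nodes$name[r])
        attr_acc[[length(keys)]] <- a %||% character()
        emb_acc[length(keys)] <- list(e)   # list(): keep NULL slots
      } else {
        old <- attr_acc[[pos]]
        if (!is.null(a) && length(a)) {
          clash <- intersect(names(a), names(old))
          clash <- clash[old[clash] != a[clash]]
          if (length(clash))
            conflicts[[length(conflicts) + 1L]] <- data.frame(
              type = types[pos], name = nms[pos], attribute = clash,
              kept = unname(old[clash]), discarded = unname(a[clash]),
              stringsAsFactors = FALSE)
          attr_acc[[pos]] <- c(old, a[setdiff(names(a), names(old))])
        }
        if (is.null(emb_acc[[pos]]) && !is.null(e)) emb_acc[pos] <- list(e)
      }
    }
  }
  ord <- order(types, nms, method = "radix")
  new_id <- integer(length(keys)); new_id[ord] <- seq_along(keys)

  out <- kg_new(sch)
  out$nodes <- data.frame(id = seq_along(keys),
                          type = types[ord], name = nms[ord],
                          stringsAsFactors = FALSE)
  for (k in seq_along(keys)) {
    if (length(attr_acc[[k]]))
      out$node_attrs[[as.character(new_id[k])]] <- attr_acc[[k]]
    if (!is.null(emb_acc[[k]]))
      out$embeddings[[as.character(new_id[k])]] <- emb_acc[[k]]
  }
  if (length(out$embeddings))
    out$embedding_dim <- length(out$embeddings[[1]])

  tr <- do.call(rbind, lapply(graphs, function(g) {
    if (!nrow(g$triples)) return(NULL)
    key_h <- paste0(kg_node_type(g, g$triples$head), "\r",
                    kg_node_name(g, g$triples$head))
    key_t <- paste0(kg_node_type(g, g$triples$tail), "\r",
                    kg_node_name(g, g$triples$tail))
    data.frame(head = new_id[match(key_h, keys)],
               relation = g$triples$relation,
               tail = new_id[match(key_t, keys)],
               stringsAsFactors = FALSE)
  }))
  if (is.null(tr)) tr <- out$triples
  tr <- unique(tr)
  tr <- tr[order(tr$head, tr$relation, tr$tail), , drop = FALSE]
  rownames(tr) <- NULL
  out$triples <- tr
  if (length(conflicts))
    attr(out, "conflicts") <- do.call(rbind, conflicts)
  out
}

#' Adjacency list of a knowledge graph
#'
#' Builds `A(v_i) = { v_j : (v_i, v_j) in R }` for random walks. By the
#' package's walk convention triples are treated as undirected (configurable
#' via `directed`). Neighbor lists are sorted and duplicate-free.
#'
#' @param kg a `knowledge_graph`.
#' @param relations optional character vector restricting to these relation
#'   names.
#' @param directed if `TRUE`, only head-to-tail edges are used.
#' @return named list: node id (as character) -> sorted integer neighbor ids.
#'   Nodes without neighbors map to `integer(0)`.
#' @export
kg_adjacency <- function(kg, relations = NULL, directed = FALSE) {
  stopifnot(inherits(kg, "knowledge_graph"))
  tr <- kg$triples
  if (!is.null(relations)) tr <- tr[tr$relation %in% relations, , drop = FALSE]
  ids <- sort(kg$nodes$id)
  adj <- stats::setNames(rep(list(integer()), length(ids)), as.character(ids))
  if (nrow(tr)) {
    from <- tr$head; to <- tr$tail
    if (!directed) { from <- c(from, tr$tail); to <- c(to, tr$head) }
    sp <- split(to, from)
    for (k in names(sp)) adj[[k]] <- sort(unique(as.integer(sp[[k]])))
  }
  adj
}

# Restrict a graph to the given node types (induced subgraph).
kg_subgraph_types <- function(kg, types) {
  keep <- kg$nodes$id[kg$nodes$type %in% types]
  out <- kg
  out$nodes <- kg$nodes[kg$nodes$id %in% keep, , drop = FALSE]
  out$triples <- kg$triples[kg$triples$head %in% keep &
                              kg$triples$tail %in% keep, , drop = FALSE]
  out$node_attrs <- kg$node_attrs[names(kg$node_attrs) %in% as.character(keep)]
  out$embeddings <- kg$embeddings[names(kg$embeddings) %in% as.character(keep)]
  rownames(out$nodes) <- rownames(out$triples) <- NULL
  out
}
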