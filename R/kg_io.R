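#' Read and write knowledge graphs in standard formats
#'
#' Supported formats:
#' \describe{
#'   \item{`jsonl`}{JSON Lines. Node records
#'     `{"id", "type", "name", "attributes"?, "embedding"?}` and triple
#'     records `{"head", "relation", "tail"}` (head/tail are node ids) in one
#'     file; node records must precede the triples that use them. A triples-
#'     only file (records with string `head`/`tail` names and no node
#'     records) is accepted: node types are inferred from the relation
#'     signature.}
#'   \item{`graphml`}{GraphML via igraph; attributes and embeddings are
#'     carried as JSON-encoded string attributes.}
#'   \item{`csv`}{node + edge CSV pair shaped for bulk import into graph
#'     databases: `<path>.nodes.csv` with columns `nodeId,type,name` and
#'     `<path>.edges.csv` with `startId,relation,endId`. Attributes and
#'     embeddings are not carried.}
#' }
#' `write_kg` then `read_kg` is the identity on nodes, triples, attributes
#' and embeddings for `jsonl` and `graphml`.
#'
#' @param path file path (for `csv`, the common prefix of the two files).
#' @param format one of `"jsonl"`, `"graphml"`, `"csv"`.
#' @param schema a [kg_schema] used to validate; default built-in.
#' @param kg a `knowledge_graph`.
#' @return `read_kg` returns a `knowledge_graph`; `write_kg` returns `path`
#'   invisibly.
#' @export
read_kg <- function(path, format = c("jsonl", "graphml", "csv"),
                    schema = default_schema()) {
  format <- match.arg(format)
  switch(format,
         jsonl = read_kg_jsonl(path, schema),
         graphml = read_kg_graphml(path, schema),
         csv = read_kg_csv(path, schema))
}

#' @rdname read_kg
#' @export
write_kg <- function(kg, path, format = c("jsonl", "graphml", "csv")) {
  format <- match.arg(format)
  switch(format,
         jsonl = write_kg_jsonl(kg, path),
         graphml = write_kg_graphml(kg, path),
         csv = write_kg_csv(kg, path))
  invisible(path)
}

read_kg_jsonl <- function(path, schema = default_schema()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kg <- kg_new(schema)
  name_ids <- list()   # "type\rname" -> id used for triples-only files
  for (ln in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[ln]),
                    error = function(e)
                      stopf("parse error at line %d: %s", ln, conditionMessage(e)))
    if (!is.null(rec$head)) {
      rel <- as.character(rec$relation)
      sig <- schema_relation_types(schema, rel)
      if (is.null(sig)) stopf("schema error at line %d: unknown relation '%s'",
                              ln, rel)
      endpoint <- function(x, ty) {
        if (is.character(x)) {
          id <- kg_find_node(kg, ty, x)
          if (is.na(id)) {
            res <- kg_add_nodes(kg, ty, x)
            kg <<- res$kg; id <- res$ids
          }
          id
        } else as.integer(x)
      }
      h <- endpoint(rec$head, sig$head_type)
      t <- endpoint(rec$tail, sig$tail_type)
      kg <- tryCatch(kg_add_triples(kg, h, rel, t),
                     error = function(e)
                       stopf("line %d: %s", ln, conditionMessage(e)))
    } else if (!is.null(rec$type) && !is.null(rec$name)) {
      attrs <- NULL
      if (!is.null(rec$attributes) && length(rec$attributes))
        attrs <- list(unlist(rec$attributes))
      res <- kg_add_nodes(kg, as.character(rec$type), as.character(rec$name),
                          attrs)
      kg <- res$kg
      if (!is.null(rec$id) && as.integer(rec$id) != res$ids) {
        # honor stored ids by remapping the just-added node
        kg$nodes$id[kg$nodes$id == res$ids] <- as.integer(rec$id)
        key <- as.character(res$ids)
        if (!is.null(kg$node_attrs[[key]])) {
          kg$node_attrs[[as.character(rec$id)]] <- kg$node_attrs[[key]]
          kg$node_attrs[[key]] <- NULL
        }
      }
      if (!is.null(rec$embedding) && length(rec$embedding)) {
        id <- as.character(rec$id %||% res$ids)
        kg$embeddings[[id]] <- as.numeric(rec$embedding)
      }
    } else {
      stopf("parse error at line %d: record is neither node nor triple", ln)
    }
  }
  if (length(kg$embeddings)) kg$embedding_dim <- length(kg$embeddings[[1]])
  kg_validate(kg)
  kg
}

write_kg_jsonl <- function(kg, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  ord <- order(kg$nodes$id)
  for (r in ord) {
    id <- kg$nodes$id[r]
    rec <- list(id = id, type = kg$nodes$type[r], name = kg$nodes$name[r])
    a <- kg$node_attrs[[as.character(id)]]
    if (!is.null(a) && length(a)) rec$attributes <- as.list(a)
    e <- kg$embeddings[[as.character(id)]]
    if (!is.null(e)) rec$embedding <- e
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  tr <- kg$triples[order(kg$triples$head, kg$triples$relation,
                         kg$triples$tail), , drop = FALSE]
  for (r in seq_len(nrow(tr)))
    writeLines(jsonlite::toJSON(list(head = tr$head[r],
                                     relation = tr$relation[r],
                                     tail = tr$tail[r]),
                                auto_unbox = TRUE), con)
  invisible(path)
}

kg_to_igraph <- function(kg) {
  ord <- order(kg$nodes$id)
  vattr <- vapply(kg$nodes$id[ord], function(id) {
    a <- kg$node_attrs[[as.character(id)]]
    if (is.null(a) || !length(a)) "" else
      as.character(jsonlite::toJSON(as.list(a), auto_unbox = TRUE))
  }, "")
  vemb <- vapply(kg$nodes$id[ord], function(id) {
    e <- kg$embeddings[[as.character(id)]]
    if (is.null(e)) "" else
      as.character(jsonlite::toJSON(e, digits = NA))
  }, "")
  g <- igraph::make_empty_graph(n = nrow(kg$nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(kg$nodes$id[ord]))
  g <- igraph::set_vertex_attr(g, "type", value = kg$nodes$type[ord])
  g <- igraph::set_vertex_attr(g, "canonical", value = kg$nodes$name[ord])
  g <- igraph::set_vertex_attr(g, "attributes", value = vattr)
  g <- igraph::set_vertex_attr(g, "embedding", value = vemb)
  if (nrow(kg$triples)) {
    idx <- match(kg$triples$head, kg$nodes$id[ord])
    jdx <- match(kg$triples$tail, kg$nodes$id[ord])
    g <- igraph::add_edges(g, rbind(idx, jdx),
                           relation = kg$triples$relation)
  }
  g
}

write_kg_graphml <- function(kg, path) {
  igraph::write_graph(kg_to_igraph(kg), path, format = "graphml")
  invisible(path)
}

read_kg_graphml <- function(path, schema = default_schema()) {
  g <- igraph::read_graph(path, format = "graphml")
  kg <- kg_new(schema)
  ids <- as.integer(igraph::vertex_attr(g, "name"))
  kg$nodes <- data.frame(id = ids,
                         type = igraph::vertex_attr(g, "type"),
                         name = igraph::vertex_attr(g, "canonical"),
                         stringsAsFactors = FALSE)
  vattr <- igraph::vertex_attr(g, "attributes")
  vemb <- igraph::vertex_attr(g, "embedding")
  for (i in seq_along(ids)) {
    if (nzchar(vattr[i]))
      kg$node_attrs[[as.character(ids[i])]] <-
        unlist(jsonlite::fromJSON(vattr[i]))
    if (nzchar(vemb[i]))
      kg$embeddings[[as.character(ids[i])]] <-
        as.numeric(jsonlite::fromJSON(vemb[i]))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    kg$triples <- data.frame(head = as.integer(el[, 1]),
                             relation = igraph::edge_attr(g, "relation"),
                             tail = as.integer(el[, 2]),
                             stringsAsFactors = FALSE)
  }
  ord <- order(kg$nodes$id)
  kg$nodes <- kg$nodes[ord, , drop = FALSE]
  rownames(kg$nodes) <- NULL
  if (length(kg$embeddings)) kg$embedding_dim <- length(kg$embeddings[[1]])
  kg_validate(kg)
  kg
}

write_kg_csv <- function(kg, path) {
  nodes <- kg$nodes[order(kg$nodes$id), c("id", "type", "name")]
  names(nodes) <- c("nodeId", "type", "name")
  utils::write.csv(nodes, paste0(path, ".nodes.csv"), row.names = FALSE)
  edges <- kg$triples[order(kg$triples$head, kg$triples$relation,
                            kg$triples$tail), , drop = FALSE]
  names(edges) <- c("startId", "relation", "endId")
  utils::write.csv(edges, paste0(path, ".edges.csv"), row.names = FALSE)
  invisible(path)
}

read_kg_csv <- function(path, schema = default_schema()) {
  nodes <- utils::read.csv(paste0(path, ".nodes.csv"),
                           stringsAsFactors = FALSE)
  edges <- utils::read.csv(paste0(path, ".edges.csv"),
                           stringsAsFactors = FALSE)
  kg <- kg_new(schema)
  kg$nodes <- data.frame(id = as.integer(nodes$nodeId), type = nodes$type,
                         name = nodes$name, stringsAsFactors = FALSE)
  if (nrow(edges))
    kg$triples <- data.frame(head = as.integer(edges$startId),
                             relation = edges$relation,
                             tail = as.integer(edges$endId),
                             stringsAsFactors = FALSE)
  kg_validate(kg)
  kg
}
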